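# internal helpers

# Run code with a temporarily seeded RNG, restoring global state afterwards.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive k reproducible child seeds from one parent seed
child_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  if (any(dim(mask) < 1L)) stop(sprintf("`%s` has empty dimensions", arg), call. = FALSE)
  invisible(mask)
}
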