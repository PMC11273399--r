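#' Herd population parameters for the synthetic generator
#'
#' Describes the biometry distribution of a finishing-pig herd: truncated
#' normal marginals for body length, hip width, body height and hip height,
#' a shared latent size factor that induces positive trait correlations, and
#' an allometric law that maps body dimensions to live weight. The defaults
#' reproduce the summary statistics of a 39-pig White York herd in the
#' 100-150 kg finishing range (mean weight 122.81 kg).
#'
#' Weight is generated as
#' \deqn{W = s \cdot BL^{a} HW^{b} Hb^{c} e^{\varepsilon}}
#' with the scale \eqn{s} calibrated so that the trait means map exactly to
#' the mean weight. The log-scale residual \eqn{\varepsilon} models body
#' condition: part of it is coupled to the pig's relative width minus its
#' relative length, so that, as observed in real herds, slender pigs are
#' lighter than compact pigs of the same frame size. Weights are clamped to
#' the observed herd range.
#'
#' @param traits Data frame with columns `trait`, `mean`, `sd`, `min`, `max`
#'   for `weight`, `body_length`, `hip_width`, `body_height`, `hip_height`.
#'   Units: kg for weight, cm elsewhere.
#' @param trait_correlation Pairwise correlation between the four linear
#'   traits, induced by a shared latent size factor. In `[0, 1)`.
#' @param allometry List with elements `exp_bl`, `exp_hw`, `exp_hb`
#'   (allometric exponents), `noise_sd` (SD of \eqn{\varepsilon}, log scale),
#'   `condition_coupling` (fraction, in `[0, 1]`, of \eqn{\varepsilon}
#'   carried by the relative-width-minus-relative-length shape residual) and
#'   optionally `scale`; when `scale` is `NULL` it is calibrated from the
#'   trait means.
#' @return An object of class `pigwt_population`.
#' @examples
#' pop <- pig_population()
#' pop$allometry$scale
#' @export
pig_population <- function(traits = NULL,
                           trait_correlation = 0.6,
                           allometry = list()) {
  default_traits <- tibble::tribble(
    ~trait,         ~mean,  ~sd,  ~min, ~max,
    "weight",       122.81, 7.86, 104,  138,
    "body_length",  126,    5.79, 108,  137,
    "hip_width",    34.28,  1.72, 30,   38,
    "body_height",  69.4,   2.00, 65,   74,
    "hip_height",   75.13,  2.55, 70,   82
  )
  traits <- traits %||% default_traits
  traits <- tibble::as_tibble(traits)
  needed <- default_traits$trait
  if (!all(needed %in% traits$trait))
    stop("`traits` must contain rows for: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (any(traits$sd < 0)) stop("trait SD must be non-negative", call. = FALSE)
  if (any(traits$min >= traits$mean | traits$mean >= traits$max))
    stop("each trait needs min < mean < max", call. = FALSE)
  if (trait_correlation < 0 || trait_correlation >= 1)
    stop("`trait_correlation` must be in [0, 1)", call. = FALSE)

  allo <- utils::modifyList(
    list(scale = NULL, exp_bl = 1, exp_hw = 1, exp_hb = 1,
         noise_sd = 0.03, condition_coupling = 0.8),
    allometry
  )
  if (allo$noise_sd < 0) stop("allometric noise SD must be >= 0", call. = FALSE)
  if (allo$condition_coupling < 0 || allo$condition_coupling > 1)
    stop("`condition_coupling` must be in [0, 1]", call. = FALSE)
  tmean <- function(tr) traits$mean[traits$trait == tr]
  if (is.null(allo$scale)) {
    allo$scale <- tmean("weight") /
      (tmean("body_length")^allo$exp_bl *
         tmean("hip_width")^allo$exp_hw *
         tmean("body_height")^allo$exp_hb)
  }
  structure(
    list(traits = traits, trait_correlation = trait_correlation,
         allometry = allo),
    class = "pigwt_population"
  )
}

#' @export
print.pigwt_population <- function(x, ...) {
  cat("<pigwt_population>\n")
  print(x$traits)
  cat(sprintf("trait correlation r = %.2f; allometric scale s = %.6g; noise SD = %.3f\n",
              x$trait_correlation, x$allometry$scale, x$allometry$noise_sd))
  invisible(x)
}

#' Sample pig biometry records
#'
#' Draws `n_pigs` pigs from the population model: the four linear traits come
#' from truncated normals correlated through a shared latent size factor
#' (out-of-bounds pigs are redrawn), and weight follows the allometric law
#' with a body-condition residual, clamped to the herd's weight range.
#'
#' @param n_pigs Number of pigs (>= 1).
#' @param params A [pig_population()] object.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A tibble with columns `pig_id`, `weight_kg`, `body_length_cm`,
#'   `hip_width_cm`, `body_height_cm`, `hip_height_cm`.
#' @examples
#' sample_biometry(5, seed = 1)
#' @export
sample_biometry <- function(n_pigs, params = pig_population(), seed = 1) {
  stopifnot(inherits(params, "pigwt_population"))
  if (!is.numeric(n_pigs) || n_pigs < 1) stop("`n_pigs` must be >= 1", call. = FALSE)
  n_pigs <- as.integer(n_pigs)
  tr <- params$traits
  row_of <- function(t) tr[tr$trait == t, ]
  lin <- lapply(c("body_length", "hip_width", "body_height", "hip_height"), row_of)
  names(lin) <- c("bl", "hw", "hb", "hh")
  r <- params$trait_correlation
  a <- params$allometry

  local_seed(seed, {
    draw <- function(n) {
      u <- stats::rnorm(n)
      e <- matrix(stats::rnorm(n * 4L), n, 4L)
      vals <- matrix(NA_real_, n, 4L)
      for (k in 1:4) {
        vals[, k] <- lin[[k]]$mean +
          lin[[k]]$sd * (sqrt(r) * u + sqrt(1 - r) * e[, k])
      }
      list(vals = vals, e = e)
    }
    d <- draw(n_pigs)
    ok <- function(d) {
      inb <- rep(TRUE, nrow(d$vals))
      for (k in 1:4)
        inb <- inb & d$vals[, k] >= lin[[k]]$min & d$vals[, k] <= lin[[k]]$max
      inb
    }
    inb <- ok(d)
    guard <- 0L
    while (!all(inb) && guard < 1000L) {
      redo <- draw(sum(!inb))
      d$vals[!inb, ] <- redo$vals
      d$e[!inb, ] <- redo$e
      inb <- ok(d)
      guard <- guard + 1L
    }
    if (!all(inb))
      stop("trait truncation bounds too tight: rejection sampling failed",
           call. = FALSE)

    bl <- d$vals[, 1]; hw <- d$vals[, 2]; hb <- d$vals[, 3]; hh <- d$vals[, 4]
    # body-condition residual: relatively wide, short pigs are heavier
    cc <- a$condition_coupling
    shape <- (d$e[, 2] - d$e[, 1]) / sqrt(2)
    eps <- a$noise_sd * (cc * shape + sqrt(1 - cc^2) * stats::rnorm(n_pigs))
    w_row <- row_of("weight")
    w <- a$scale * bl^a$exp_bl * hw^a$exp_hw * hb^a$exp_hb * exp(eps)
    w <- pmin(pmax(w, w_row$min), w_row$max)

    tibble::tibble(
      pig_id = sprintf("pig%03d", seq_len(n_pigs)),
      weight_kg = w,
      body_length_cm = bl,
      hip_width_cm = hw,
      body_height_cm = hb,
      hip_height_cm = hh
    )
  })
}
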