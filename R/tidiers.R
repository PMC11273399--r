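#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' Broom-style summaries of fitted objects and reports: `tidy()` returns one
#' row per component (model term, boosting round, strategy-method cell);
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted `pigwt_*` object.
#' @param ... Unused.
#' @name pigwt-tidiers
NULL

#' @rdname pigwt-tidiers
#' @method tidy pigwt_lr
#' @export
tidy.pigwt_lr <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname pigwt-tidiers
#' @method tidy pigwt_lasso
#' @export
tidy.pigwt_lasso <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$feature_names),
                 estimate = unname(x$coef))
}

#' @rdname pigwt-tidiers
#' @method tidy pigwt_gboost
#' @export
tidy.pigwt_gboost <- function(x, ...) {
  tibble::tibble(round = seq_len(x$rounds),
                 n_leaves = vapply(x$trees, function(t)
                   sum(vapply(t$nodes, function(n) n$leaf, logical(1))), numeric(1)),
                 train_rmse = x$train_rmse)
}

#' @rdname pigwt-tidiers
#' @method glance pigwt_gboost
#' @export
glance.pigwt_gboost <- function(x, ...) {
  tibble::tibble(rounds = x$rounds, shrinkage = x$shrinkage,
                 lambda = x$lambda, gamma = x$gamma,
                 base_score = x$base_score,
                 train_rmse = x$train_rmse[x$rounds])
}

#' @rdname pigwt-tidiers
#' @method glance pigwt_forest
#' @export
glance.pigwt_forest <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees)
}

#' @rdname pigwt-tidiers
#' @method tidy pigwt_report
#' @export
tidy.pigwt_report <- function(x, ...) {
  x$metrics
}

#' @rdname pigwt-tidiers
#' @method glance pigwt_report
#' @export
glance.pigwt_report <- function(x, ...) {
  best <- x$metrics[which.min(x$metrics$mae), ]
  tibble::tibble(n_frames = nrow(x$features),
                 n_train = length(x$split$train),
                 n_test = length(x$split$test),
                 split_mode = x$split$mode,
                 best_strategy = best$strategy, best_method = best$method,
                 best_mae = best$mae, best_r2 = best$r2)
}

#' @rdname pigwt-tidiers
#' @method tidy pigwt_correction
#' @export
tidy.pigwt_correction <- function(x, ...) {
  tibble::tibble(target = c("body_length_cm", "hip_width_cm", "hdep_cm"),
                 train_rmse = c(x$model_bl$train_rmse[x$model_bl$rounds],
                                x$model_hw$train_rmse[x$model_hw$rounds],
                                x$model_hdep$train_rmse[x$model_hdep$rounds]))
}
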