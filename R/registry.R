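#' The weight-regressor registry
#'
#' The ten regression methods compared by the pipeline. `XGBoost` (Newton
#' boosting), `RFR` (random forest), `Adaboost` (Adaboost.R2), `Stacking`,
#' `LR`, `Lasso` and `KRR` are native implementations; `SVR`, `MLP` and `BP`
#' are adapters over \pkg{e1071} and \pkg{nnet}.
#'
#' @return A tibble with columns `method` and `engine`.
#' @export
regressor_registry <- function() {
  tibble::tribble(
    ~method,    ~engine,
    "XGBoost",  "native Newton-boosted trees",
    "BP",       "back-propagation network (nnet adapter)",
    "Lasso",    "native coordinate-descent lasso",
    "LR",       "native least squares",
    "MLP",      "multilayer perceptron (nnet adapter)",
    "RFR",      "native random forest",
    "Stacking", "native stack (RFR + XGBoost + KRR, linear meta-learner)",
    "SVR",      "epsilon-SVR, RBF kernel (e1071 adapter)",
    "KRR",      "native kernel ridge regression",
    "Adaboost", "native Adaboost.R2 on regression trees"
  )
}

#' Fit a weight regressor by registry name
#'
#' Uniform fit interface over the ten-method registry (see
#' [regressor_registry()]). All fits are deterministic for a fixed `seed`.
#'
#' @param x Feature data frame or matrix (frames x features).
#' @param y Numeric weights (kg).
#' @param method Registry name, e.g. `"XGBoost"`, `"RFR"`, `"LR"`.
#' @param params Named list of hyperparameters forwarded to the underlying
#'   fitter (e.g. `list(rounds = 100, max_depth = 3)` for `XGBoost`,
#'   `list(penalty = 0.1)` for `Lasso`/`KRR`).
#' @param seed Integer seed for any stochastic component.
#' @return An object of class `pigwt_model`; use [predict()] on new feature
#'   rows.
#' @examples
#' d <- data.frame(a = 1:20, b = (1:20)^2)
#' m <- fit_regressor(d, 2 * d$a + 1, "LR")
#' predict(m, d[1:3, ])
#' @export
fit_regressor <- function(x, y, method, params = list(), seed = 1) {
  valid <- regressor_registry()$method
  if (length(method) != 1 || !method %in% valid)
    stop("unknown method '", paste(method, collapse = ","),
         "'; valid methods: ", paste(valid, collapse = ", "), call. = FALSE)
  X <- check_xy(x, y)
  p <- params
  cl <- colnames(X)
  fit <- switch(
    method,
    XGBoost = do.call(fit_gboost, c(list(x = X, y = y, seed = seed), p)),
    RFR = do.call(fit_random_forest, c(list(x = X, y = y, seed = seed), p)),
    LR = new_model(fit_lr_core(X, y), "lr", "LR", cl),
    Lasso = new_model(do.call(fit_lasso_core, c(list(X = X, y = y), p)),
                      "lasso", "Lasso", cl),
    KRR = new_model(do.call(fit_krr_core, c(list(X = X, y = y), p)),
                    "krr", "KRR", cl),
    Adaboost = new_model(do.call(fit_adaboost_r2,
                                 c(list(x = X, y = y, seed = seed), p)),
                         "adaboost", "Adaboost", cl),
    Stacking = new_model(do.call(fit_stacking_core,
                                 c(list(X = X, y = y, seed = seed), p)),
                         "stacking", "Stacking", cl),
    SVR = new_model(do.call(fit_svr_core, c(list(X = X, y = y, seed = seed), p)),
                    "svr", "SVR", cl),
    MLP = new_model(fit_nnet_core(X, y, size = p$size %||% 16,
                                  decay = p$decay %||% 1e-3,
                                  maxit = p$maxit %||% 800, seed = seed),
                    "nnet", "MLP", cl),
    BP = new_model(fit_nnet_core(X, y, size = p$size %||% 8,
                                 decay = p$decay %||% 1e-2,
                                 maxit = p$maxit %||% 500, seed = seed),
                   "nnet", "BP", cl)
  )
  fit
}

#' @export
predict.pigwt_lr <- function(object, newdata, ...) {
  predict_lr_core(object, model_matrix(object, newdata))
}

#' @export
predict.pigwt_lasso <- function(object, newdata, ...) {
  predict_lr_core(object, model_matrix(object, newdata))
}

#' @export
predict.pigwt_krr <- function(object, newdata, ...) {
  predict_krr_core(object, model_matrix(object, newdata))
}

#' @export
predict.pigwt_adaboost <- function(object, newdata, ...) {
  X <- model_matrix(object, newdata)
  if (nrow(X) == 0) return(numeric(0))
  predict_adaboost_r2(object, X)
}

#' @export
predict.pigwt_stacking <- function(object, newdata, ...) {
  X <- model_matrix(object, newdata)
  if (nrow(X) == 0) return(numeric(0))
  predict_stacking_core(object, X)
}

#' @export
predict.pigwt_svr <- function(object, newdata, ...) {
  predict_svr_core(object, model_matrix(object, newdata))
}

#' @export
predict.pigwt_nnet <- function(object, newdata, ...) {
  X <- model_matrix(object, newdata)
  if (nrow(X) == 0) return(numeric(0))
  predict_nnet_core(object, X)
}

#' @export
print.pigwt_model <- function(x, ...) {
  cat(sprintf("<pigwt_model: %s> features: %s\n", x$method,
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}
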