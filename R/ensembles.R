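#' Fit a random-forest regressor
#'
#' Bagged regression trees: each tree is trained on a seeded bootstrap
#' resample with per-split feature subsampling; the forest prediction is
#' exactly the arithmetic mean of the tree predictions.
#'
#' @inheritParams fit_tree
#' @param n_trees Number of trees (default 200).
#' @param bootstrap Draw a bootstrap resample per tree (default `TRUE`).
#' @param features_per_split Fraction of features tried at each split
#'   (default 1/3).
#' @param min_samples_leaf Minimum rows per leaf (default 5, the usual
#'   regression-forest node size).
#' @param seed Seed controlling resampling and feature subsampling.
#' @return An object of class `pigwt_forest` / `pigwt_model`.
#' @export
fit_random_forest <- function(x, y, n_trees = 200, bootstrap = TRUE,
                              features_per_split = 1 / 3, max_depth = Inf,
                              min_samples_leaf = 5, seed = 1) {
  X <- check_xy(x, y)
  if (n_trees < 1) stop("`n_trees` must be >= 1", call. = FALSE)
  n <- nrow(X)
  trees <- local_seed(seed, {
    lapply(seq_len(n_trees), function(b) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      build_tree_core(X[idx, , drop = FALSE], g = -y[idx],
                      h = rep(1, length(idx)), lambda = 0, gamma = 0,
                      max_depth = max_depth,
                      min_leaf = as.integer(min_samples_leaf),
                      features_per_split = features_per_split)
    })
  })
  new_model(list(trees = trees, n_trees = n_trees), "forest", "RFR", colnames(X))
}

#' @export
predict.pigwt_forest <- function(object, newdata, ...) {
  X <- model_matrix(object, newdata)
  if (nrow(X) == 0) return(numeric(0))
  preds <- vapply(object$trees, function(t) predict_tree_core(t, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1) mean(preds) else rowMeans(matrix(preds, nrow = nrow(X)))
}

#' Fit a gradient-boosted tree regressor (Newton boosting)
#'
#' Additive regression trees fitted by second-order (Newton) boosting of the
#' squared loss \eqn{L = \frac12 (y - \hat y)^2}: per round the gradients
#' are \eqn{g = \hat y - y} and hessians \eqn{h = 1}; a tree is grown
#' maximizing the regularized split gain
#' \deqn{\frac12\left[\frac{G_L^2}{H_L+\lambda} + \frac{G_R^2}{H_R+\lambda}
#'   - \frac{G^2}{H+\lambda}\right] - \gamma,}
#' splits with non-positive gain are rejected, leaves take the weight
#' \eqn{w^* = -G/(H+\lambda)}, and predictions are updated by
#' \eqn{\hat y \leftarrow \hat y + \eta\, w^*}. This is the learner behind
#' the "XGBoost" entry of the method registry and the feature-correction
#' stage.
#'
#' @inheritParams fit_tree
#' @param rounds Number of boosting rounds K (default 300).
#' @param shrinkage Learning rate eta in (0, 1] (default 0.1).
#' @param lambda L2 penalty on leaf weights (default 1).
#' @param gamma Per-leaf split penalty (default 0).
#' @param max_depth Tree depth per round (default 4).
#' @return An object of class `pigwt_gboost` / `pigwt_model`; element
#'   `train_rmse` traces the training RMSE per round.
#' @export
fit_gboost <- function(x, y, rounds = 300, shrinkage = 0.1, lambda = 1,
                       gamma = 0, max_depth = 4, min_samples_leaf = 1,
                       features_per_split = 1, seed = NULL) {
  X <- check_xy(x, y)
  if (rounds < 1) stop("`rounds` must be >= 1", call. = FALSE)
  if (lambda < 0 || gamma < 0) stop("`lambda` and `gamma` must be >= 0", call. = FALSE)
  if (shrinkage <= 0 || shrinkage > 1) stop("`shrinkage` must be in (0, 1]", call. = FALSE)
  n <- nrow(X)
  base <- mean(y)
  pred <- rep(base, n)
  trees <- vector("list", rounds)
  rmse <- numeric(rounds)
  h <- rep(1, n)
  local_seed(seed, {
    for (k in seq_len(rounds)) {
      g <- pred - y
      tr <- build_tree_core(X, g = g, h = h, lambda = lambda, gamma = gamma,
                            max_depth = max_depth,
                            min_leaf = as.integer(min_samples_leaf),
                            features_per_split = features_per_split)
      trees[[k]] <- tr
      pred <- pred + shrinkage * predict_tree_core(tr, X)
      rmse[k] <- sqrt(mean((y - pred)^2))
    }
  })
  new_model(list(trees = trees, base_score = base, shrinkage = shrinkage,
                 lambda = lambda, gamma = gamma, rounds = rounds,
                 train_rmse = rmse),
            "gboost", "XGBoost", colnames(X))
}

#' @export
predict.pigwt_gboost <- function(object, newdata, ...) {
  X <- model_matrix(object, newdata)
  out <- rep(object$base_score, nrow(X))
  for (tr in object$trees) out <- out + object$shrinkage * predict_tree_core(tr, X)
  out
}

# Adaboost.R2 with linear loss on regression trees
fit_adaboost_r2 <- function(x, y, n_estimators = 50, max_depth = 8,
                            min_samples_leaf = 3, seed = 1) {
  X <- check_xy(x, y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  local_seed(seed, {
    for (m in seq_len(n_estimators)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      tr <- build_tree_core(X[idx, , drop = FALSE], g = -y[idx],
                            h = rep(1, n), lambda = 0, gamma = 0,
                            max_depth = max_depth,
                            min_leaf = as.integer(min_samples_leaf),
                            features_per_split = 1)
      err <- abs(predict_tree_core(tr, X) - y)
      D <- max(err)
      if (D <= 0) { # perfect learner: keep it with a large weight and stop
        trees[[length(trees) + 1]] <- tr
        betas <- c(betas, 1e-10)
        break
      }
      L <- err / D
      Lbar <- sum(w * L)
      if (Lbar >= 0.5) {
        if (length(trees) == 0) { # keep one learner regardless
          trees[[1]] <- tr
          betas <- 1
        }
        break
      }
      beta <- Lbar / (1 - Lbar)
      trees[[length(trees) + 1]] <- tr
      betas <- c(betas, beta)
      w <- w * beta^(1 - L)
      w <- w / sum(w)
    }
  })
  list(trees = trees, log_inv_beta = log(1 / betas))
}

predict_adaboost_r2 <- function(fit, X) {
  M <- length(fit$trees)
  if (M == 1) return(predict_tree_core(fit$trees[[1]], X))
  P <- matrix(vapply(fit$trees, function(t) predict_tree_core(t, X),
                     numeric(nrow(X))), nrow = nrow(X))
  wts <- fit$log_inv_beta
  # weighted median across learners, per row
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= sum(wts) / 2)[1]]
  })
}
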