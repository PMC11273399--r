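test_that("single trees handle constants, steps, and match exhaustive split search", {
  # constant response: one leaf
  m <- fit_tree(data.frame(x = 1:10), rep(3.5, 10))
  expect_equal(predict(m, data.frame(x = c(-5, 100))), c(3.5, 3.5))
  expect_equal(length(m$tree$nodes), 1)
  # 1-D step function, depth 1: split at the step, zero training error
  x <- data.frame(z = seq(-4, 4))
  y <- as.numeric(x$z > 0)
  st <- fit_tree(x, y, max_depth = 1)
  expect_equal(predict(st, x), y)
  expect_equal(st$tree$nodes[[st$tree$root]]$threshold, 0.5)
  # random 8-row sets: chosen depth-1 split equals brute-force enumeration
  withr::with_seed(99, {
    for (i in 1:20) {
      X <- matrix(stats::rnorm(8 * 3), 8, 3)
      colnames(X) <- c("a", "b", "c")
      y8 <- stats::rnorm(8)
      t1 <- fit_tree(as.data.frame(X), y8, max_depth = 1)
      node <- t1$tree$nodes[[t1$tree$root]]
      ora <- oracle_best_split(X, y8)
      expect_equal(node$feature, ora$feature)
      expect_equal(node$threshold, ora$threshold)
    }
  })
  expect_error(fit_tree(data.frame(x = numeric(0)), numeric(0)), "empty")
})

test_that("a forest is exactly the mean of its trees and degenerates to one tree", {
  set.seed(1)
  x <- data.frame(a = runif(60), b = runif(60))
  y <- 2 * x$a - x$b + rnorm(60, 0, 0.1)
  f1 <- fit_random_forest(x, y, n_trees = 1, bootstrap = FALSE,
                          features_per_split = 1, min_samples_leaf = 1, seed = 3)
  t1 <- fit_tree(x, y, min_samples_leaf = 1)
  expect_equal(predict(f1, x), predict(t1, x))
  ff <- fit_random_forest(x, y, n_trees = 25, seed = 5)
  manual <- rowMeans(vapply(ff$trees, function(t)
    pigwt:::predict_tree_core(t, as.matrix(x)), numeric(60)))
  expect_identical(predict(ff, x), manual)
})

test_that("forests reduce held-out error relative to their median single tree", {
  set.seed(7)
  n <- 150
  x <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  y <- sin(3 * x$a) + x$b^2 + 0.3 * x$c + rnorm(n, 0, 0.2)
  tr <- 1:100; te <- 101:150
  ff <- fit_random_forest(x[tr, ], y[tr], n_trees = 100, seed = 11)
  mse <- function(p) mean((p - y[te])^2)
  forest_mse <- mse(predict(ff, x[te, ]))
  tree_mses <- vapply(ff$trees, function(t)
    mse(pigwt:::predict_tree_core(t, as.matrix(x[te, ]))), numeric(1))
  expect_lte(forest_mse, stats::median(tree_mses))
})

test_that("Newton boosting satisfies its closed forms and descends monotonically", {
  y8 <- c(3, 1, 4, 1, 5, 9, 2, 6)
  x8 <- data.frame(z = 1:8)
  # one round, single leaf, eta = 1: base + sum(y - base) / (n + lambda)
  m0 <- fit_gboost(x8, y8, rounds = 1, shrinkage = 1, lambda = 2, max_depth = 0)
  expect_equal(predict(m0, x8)[1], mean(y8) + sum(y8 - mean(y8)) / (8 + 2))
  # gamma -> infinity: every round degenerates to the single-leaf model
  set.seed(2)
  x <- data.frame(a = runif(80), b = runif(80))
  y <- x$a * 3 + rnorm(80, 0, 0.1)
  mg <- fit_gboost(x, y, rounds = 4, gamma = 1e12)
  expect_equal(length(unique(predict(mg, x))), 1)
  # training RMSE non-increasing per round with gamma = 0
  mb <- fit_gboost(x, y, rounds = 50, shrinkage = 0.3, gamma = 0)
  expect_true(all(diff(mb$train_rmse) <= 1e-12))
  expect_error(fit_gboost(x, y, rounds = 0), "rounds")
  expect_error(fit_gboost(x, y, lambda = -1), "lambda")
})

test_that("native boosting agrees with an independent exact-greedy implementation", {
  skip_if_not_installed("xgboost")
  set.seed(42)
  n <- 200
  x <- data.frame(a = runif(n), b = runif(n), c = rnorm(n))
  y <- 2 * x$a + sin(3 * x$b) + 0.5 * x$c + rnorm(n, 0, 0.05)
  mine <- fit_gboost(x, y, rounds = 40, shrinkage = 0.3, lambda = 1,
                     gamma = 0, max_depth = 3)
  dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  ref <- xgboost::xgb.train(
    params = list(eta = 0.3, max_depth = 3, lambda = 1, gamma = 0,
                  min_child_weight = 0, base_score = mean(y),
                  tree_method = "exact"),
    data = dm, nrounds = 40, verbose = 0
  )
  expect_lt(max(abs(predict(mine, x) - predict(ref, dm))), 1e-4)
})

test_that("linear baselines satisfy their closed-form limits", {
  set.seed(3)
  X <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  beta <- c(1.5, -2, 0.5)
  y <- 4 + as.matrix(X) %*% beta
  lr <- fit_regressor(X, as.vector(y), "LR")
  expect_equal(unname(lr$coef), c(4, beta), tolerance = 1e-10)
  # lasso with zero penalty equals least squares
  la0 <- fit_regressor(X, as.vector(y), "Lasso", params = list(penalty = 0))
  expect_equal(unname(la0$coef), c(4, beta), tolerance = 1e-5)
  # overwhelming penalty: all slopes zero, intercept = mean
  yn <- as.vector(y) + rnorm(40, 0, 0.1)
  laI <- fit_regressor(X, yn, "Lasso", params = list(penalty = 1e6))
  expect_equal(unname(laI$coef[-1]), c(0, 0, 0))
  expect_equal(unname(laI$coef[1]), mean(yn))
})

test_that("coordinate-descent lasso matches glmnet on standardized data", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  y <- 1 + X %*% c(2, 0, -1, 0.2) + rnorm(n, 0, 0.3)
  pen <- 0.15
  mine <- fit_regressor(as.data.frame(X), as.vector(y), "Lasso",
                        params = list(penalty = pen))
  ref <- glmnet::glmnet(X, y, alpha = 1, lambda = pen, standardize = TRUE,
                        thresh = 1e-12)
  expect_equal(unname(mine$coef[-1]), as.vector(ref$beta), tolerance = 1e-3)
})

test_that("every registry method fits, predicts row-wise and is seed-deterministic", {
  set.seed(5)
  n <- 80
  x <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  y <- 100 + 20 * x$a + 10 * x$b * x$c + rnorm(n, 0, 1)
  small <- list(XGBoost = list(rounds = 30), RFR = list(n_trees = 20),
                Adaboost = list(n_estimators = 10),
                Stacking = list(base_params = list(rfr_trees = 10,
                                                   gboost_rounds = 20)),
                MLP = list(maxit = 100), BP = list(maxit = 100))
  for (me in regressor_registry()$method) {
    p <- small[[me]] %||% list()
    m1 <- fit_regressor(x, y, me, params = p, seed = 7)
    m2 <- fit_regressor(x, y, me, params = p, seed = 7)
    p1 <- predict(m1, x)
    expect_equal(p1, predict(m2, x), tolerance = 1e-12, label = me)
    expect_length(p1, n)
    expect_true(all(is.finite(p1)), label = me)
    # duplicated rows give identical predictions
    dup <- x[rep(1, 5), ]
    expect_equal(length(unique(round(predict(m1, dup), 9))), 1, label = me)
  }
  expect_error(fit_regressor(x, y, "GBM"), "valid methods")
})

test_that("predict validates features and handles empty input", {
  set.seed(6)
  x <- data.frame(a = runif(20), b = runif(20))
  m <- fit_regressor(x, x$a * 2, "XGBoost", params = list(rounds = 10))
  expect_length(predict(m, x[0, ]), 0)
  expect_error(predict(m, data.frame(q = 1)), "missing features|expected")
  # named columns may arrive in any order
  xr <- x[, c("b", "a")]
  expect_equal(predict(m, xr), predict(m, x))
})

test_that("native models round-trip through the JSON dump", {
  set.seed(9)
  x <- data.frame(a = runif(40), b = runif(40))
  y <- 3 * x$a - x$b + rnorm(40, 0, 0.05)
  for (me in c("XGBoost", "RFR", "LR", "Lasso", "KRR", "Adaboost")) {
    p <- switch(me, XGBoost = list(rounds = 15), RFR = list(n_trees = 5),
                Adaboost = list(n_estimators = 5), list())
    m <- fit_regressor(x, y, me, params = p, seed = 2)
    back <- model_from_json(model_to_json(m))
    expect_equal(predict(back, x), predict(m, x), tolerance = 1e-10, label = me)
  }
  m <- fit_regressor(x, y, "SVR")
  expect_error(model_to_json(m), "third-party")
})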