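herd_features <- function() {
  herd <- tiny_herd()
  f <- herd$features
  # fake corrected features for assembly tests
  corr <- tibble::tibble(frame_id = f$frame_id,
                         bl_hat_cm = f$pbl_px / f$pixels_per_cm,
                         hw_hat_cm = f$phw_px / f$pixels_per_cm,
                         hdep_hat_cm = f$hdep_cm)
  list(f = f, bio = herd$plan$biometry, corr = corr)
}

test_that("strategy datasets carry the documented column sets in order", {
  h <- herd_features()
  d1 <- build_strategy_dataset(h$f, h$bio, strategy = "1")
  expect_identical(names(d1$x),
                   c("area_px2", "per_px", "pbl_px", "phw_px", "ecc", "dev"))
  d1b <- build_strategy_dataset(h$f, h$bio, strategy = "1b")
  expect_identical(names(d1b$x),
                   c("area_px2", "per_px", "pbl_px", "phw_px", "ecc"))
  d2 <- build_strategy_dataset(h$f, h$bio, h$corr, strategy = "2")
  expect_identical(names(d2$x),
                   c("area_px2", "per_px", "bl_hat_cm", "hw_hat_cm", "ecc", "dev"))
  d3 <- build_strategy_dataset(h$f, h$bio, h$corr, strategy = "3")
  expect_identical(names(d3$x)[7], "hdep_hat_cm")
  expect_equal(length(d3$y), nrow(h$f))
  expect_error(build_strategy_dataset(h$f, h$bio, strategy = "2"),
               "corrected")
})

test_that("the 7:3 split uses the floor convention and is reproducible", {
  sp <- split_frames(1505, seed = 4)
  expect_equal(length(sp$train), 1053) # floor(0.7 * 1505)
  expect_equal(length(sp$test), 452)
  expect_equal(sort(c(sp$train, sp$test)), 1:1505)
  expect_identical(split_frames(1505, seed = 4), sp)
  expect_false(identical(split_frames(1505, seed = 5)$train, sp$train))
  expect_error(split_frames(1), "at least 2")
})

test_that("by-pig splits keep every pig on one side", {
  h <- herd_features()
  d1 <- build_strategy_dataset(h$f, h$bio, strategy = "1")
  sp <- split_frames(d1, mode = "pig", seed = 2)
  expect_length(intersect(unique(d1$pig_id[sp$train]),
                          unique(d1$pig_id[sp$test])), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(d1$y))
})

test_that("grid search evaluates every configuration by k-fold RMSE", {
  set.seed(12)
  x <- data.frame(a = runif(60), b = runif(60))
  y <- 5 * x$a + rnorm(60, 0, 0.2)
  one <- grid_search_cv(x, y, "XGBoost", grid = list(list(rounds = 10)), seed = 1)
  expect_equal(one$best_params, list(rounds = 10))
  grid <- list(list(penalty = 10), list(penalty = 0.001))
  gs <- grid_search_cv(x, y, "Lasso", grid = grid, k = 5, seed = 3)
  expect_equal(gs$best_params$penalty, 0.001)
  expect_equal(nrow(gs$results), 2)
  # independent re-evaluation of every grid point reproduces the choice
  folds <- pigwt:::make_folds(60, 5, 3)
  expect_equal(as.vector(table(folds)), rep(12, 5)) # balanced folds
  re <- vapply(grid, function(p) {
    mean(vapply(1:5, function(f) {
      m <- fit_regressor(x[folds != f, ], y[folds != f], "Lasso", params = p,
                         seed = 3)
      sqrt(mean((predict(m, x[folds == f, ]) - y[folds == f])^2))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(which.min(re)), 2)
  expect_equal(unname(gs$results$cv_rmse), unname(re), tolerance = 1e-10)
})

test_that("evaluation metrics match hand arithmetic and a dual transcription", {
  perfect <- evaluate_predictions(c(2, 3, 4), c(2, 3, 4))
  expect_equal(unlist(perfect), c(mae = 0, mape = 0, rmse = 0, r2 = 1))
  hand <- evaluate_predictions(c(100, 120), c(110, 110))
  expect_equal(hand$mae, 10)
  expect_equal(hand$rmse, 10)
  expect_equal(hand$mape, 100 / 2 * (10 / 100 + 10 / 120)) # 9.1667%
  expect_equal(hand$mape, 9.16667, tolerance = 1e-5)
  withr::with_seed(31, {
    for (i in 1:10) {
      y <- runif(50, 80, 150)
      p <- y + rnorm(50, 0, 5)
      got <- evaluate_predictions(y, p)
      want <- oracle_metrics(y, p)
      expect_equal(unlist(got), want, tolerance = 1e-12)
      expect_lte(got$mae, got$rmse)
      expect_lte(got$r2, 1)
    }
  })
  expect_error(evaluate_predictions(c(0, 1), c(1, 1)), "zeros")
  expect_error(evaluate_predictions(1:3, 1:2), "equal")
  # the alternative baseline convention divides by spread around mean(pred)
  alt <- evaluate_predictions(c(100, 120), c(110, 110),
                              r2_baseline = "predicted")
  expect_equal(alt$r2, 1 - 200 / sum((110 - c(100, 120))^2))
})

test_that("pearson screen returns per-feature correlations and flags degeneracy", {
  w <- c(90, 100, 110, 130)
  f <- tibble::tibble(same = w, opposite = -w, flat = rep(1, 4))
  expect_warning(out <- pearson_screen(f, w), "zero-variance")
  expect_equal(out$r[out$feature == "same"], 1)
  expect_equal(out$r[out$feature == "opposite"], -1)
  expect_true(is.na(out$r[out$feature == "flat"]))
  expect_error(pearson_screen(f[1:2, ], w[1:2]), "at least 3")
})

test_that("the synthetic herd reproduces the field's correlation sign pattern", {
  h <- herd_features()
  w <- dplyr::left_join(h$f, h$bio, by = "pig_id")$weight_kg
  sc <- pearson_screen(h$f[, c("area_px2", "per_px", "pbl_px", "phw_px",
                               "ecc", "dev")], w)
  r <- setNames(sc$r, sc$feature)
  expect_gt(r[["area_px2"]], 0)
  expect_gt(r[["per_px"]], 0)
  expect_gt(r[["pbl_px"]], 0)
  expect_gt(r[["phw_px"]], 0)
  expect_lt(r[["dev"]], 0)
})

test_that("run_pipeline produces one finite metrics row per strategy-method pair", {
  rep <- run_pipeline(list(n_pigs = 8, frames_per_pig = 3, seed = 5,
                           strategies = c("1", "2"),
                           methods = c("LR", "XGBoost"),
                           params = list(XGBoost = list(rounds = 40))))
  expect_equal(nrow(rep$metrics), 4)
  expect_equal(nrow(dplyr::distinct(rep$metrics[, c("strategy", "method")])), 4)
  expect_true(all(is.finite(unlist(rep$metrics[, c("mae", "mape", "rmse", "r2")]))))
  expect_equal(sort(unique(rep$predictions$strategy)), c("1", "2"))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_predictions(rep), "ggplot")
  expect_s3_class(plot_correlations(rep), "ggplot")
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("no test-pig information leaks into by-pig-mode training", {
  h <- herd_features()
  d <- build_strategy_dataset(h$f, h$bio, strategy = "1")
  sp <- split_frames(d, mode = "pig", seed = 6)
  fit_and_predict <- function(bio) {
    dd <- build_strategy_dataset(h$f, bio, strategy = "1")
    m <- fit_regressor(dd$x[sp$train, ], dd$y[sp$train], "XGBoost",
                       params = list(rounds = 30), seed = 1)
    predict(m, dd$x[sp$test, ])
  }
  # corrupting the test pigs' recorded weights must not move test predictions
  bio2 <- h$bio
  test_pigs <- unique(d$pig_id[sp$test])
  bio2$weight_kg[bio2$pig_id %in% test_pigs] <- 999
  expect_identical(fit_and_predict(h$bio), fit_and_predict(bio2))
})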