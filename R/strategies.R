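#' Assemble a strategy dataset
#'
#' The three feature-combination strategies (plus the five-feature
#' ablation):
#' \describe{
#'   \item{`"1"`}{raw image features `(Area, Per, PBL, PHW, Ecc, Dev)`.}
#'   \item{`"1b"`}{the ablation: strategy 1 without `Dev`.}
#'   \item{`"2"`}{corrected body size: `(Area, Per, BL_hat, HW_hat, Ecc,
#'     Dev)`.}
#'   \item{`"3"`}{strategy 2 plus the estimated depth `Hdep_hat`.}
#' }
#'
#' @param features Per-frame feature tibble with `frame_id`, `pig_id` and
#'   the six feature columns.
#' @param biometry Per-pig tibble supplying `weight_kg`.
#' @param corrected Per-frame corrected features ([apply_correction()]
#'   output); required for strategies `"2"` and `"3"`.
#' @param strategy One of `"1"`, `"1b"`, `"2"`, `"3"`.
#' @return An object of class `pigwt_strategy_dataset`: list with `x`
#'   (feature tibble, fixed column order), `y` (weights, kg), `frame_id`,
#'   `pig_id`, `strategy`.
#' @export
build_strategy_dataset <- function(features, biometry, corrected = NULL,
                                   strategy = c("1", "1b", "2", "3")) {
  strategy <- match.arg(as.character(strategy), c("1", "1b", "2", "3"))
  cols <- switch(strategy,
    "1"  = c("area_px2", "per_px", "pbl_px", "phw_px", "ecc", "dev"),
    "1b" = c("area_px2", "per_px", "pbl_px", "phw_px", "ecc"),
    "2"  = c("area_px2", "per_px", "bl_hat_cm", "hw_hat_cm", "ecc", "dev"),
    "3"  = c("area_px2", "per_px", "bl_hat_cm", "hw_hat_cm", "ecc", "dev",
             "hdep_hat_cm")
  )
  tbl <- features
  if (strategy %in% c("2", "3")) {
    if (is.null(corrected))
      stop("strategies 2 and 3 need `corrected` features", call. = FALSE)
    tbl <- dplyr::left_join(tbl,
                            corrected[, c("frame_id", setdiff(names(corrected),
                                                              c("frame_id", "pig_id")))],
                            by = "frame_id")
  }
  missing_cols <- setdiff(cols, names(tbl))
  if (length(missing_cols) > 0)
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tbl <- dplyr::left_join(tbl, biometry[, c("pig_id", "weight_kg")], by = "pig_id")
  if (anyNA(tbl$weight_kg))
    stop("some frames have no weight in `biometry`", call. = FALSE)
  structure(
    list(x = tibble::as_tibble(tbl[, cols]), y = tbl$weight_kg,
         frame_id = tbl$frame_id, pig_id = tbl$pig_id, strategy = strategy),
    class = "pigwt_strategy_dataset"
  )
}

#' @export
print.pigwt_strategy_dataset <- function(x, ...) {
  cat(sprintf("<pigwt_strategy_dataset> strategy %s: %d frames x %d features [%s]\n",
              x$strategy, nrow(x$x), ncol(x$x), paste(names(x$x), collapse = ", ")))
  invisible(x)
}

#' Train/test split plan
#'
#' Seeded random split of frames into training and test sets (default 7:3,
#' train size `floor(ratio * n)`). `mode = "pig"` keeps all frames of a pig
#' on the same side (no identity leakage), sampling `floor(ratio * n_pigs)`
#' pigs into the training side; `mode = "frame"` splits frames independently
#' of pig identity, mirroring a frame-level acquisition split.
#'
#' @param dataset A `pigwt_strategy_dataset`, or an integer number of rows
#'   (frame mode only).
#' @param ratio Training fraction (default 0.7).
#' @param mode `"frame"` or `"pig"`.
#' @param seed Integer seed.
#' @return An object of class `pigwt_split`: list with integer vectors
#'   `train` and `test` (disjoint, covering all rows), `mode`, `ratio`.
#' @export
split_frames <- function(dataset, ratio = 0.7, mode = c("frame", "pig"),
                         seed = 1) {
  mode <- match.arg(mode)
  if (is.numeric(dataset) && length(dataset) == 1) {
    n <- as.integer(dataset)
    pig_id <- NULL
  } else {
    stopifnot(inherits(dataset, "pigwt_strategy_dataset"))
    n <- length(dataset$y)
    pig_id <- dataset$pig_id
  }
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  if (mode == "frame") {
    if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
    n_train <- floor(ratio * n)
    if (n_train < 1 || n_train >= n) stop("degenerate split sizes", call. = FALSE)
    train <- local_seed(seed, sort(sample.int(n, n_train)))
  } else {
    if (is.null(pig_id)) stop("by-pig mode needs a dataset with pig ids", call. = FALSE)
    pigs <- unique(pig_id)
    if (length(pigs) < 2) stop("by-pig mode needs at least 2 pigs", call. = FALSE)
    k <- floor(ratio * length(pigs))
    if (k < 1 || k >= length(pigs)) stop("degenerate split sizes", call. = FALSE)
    tr_pigs <- local_seed(seed, sample(pigs, k))
    train <- which(pig_id %in% tr_pigs)
  }
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 ratio = ratio, mode = mode, seed = seed),
            class = "pigwt_split")
}

#' Regression evaluation metrics
#'
#' The four standard metrics:
#' \deqn{MAE = \frac1M \sum |\hat y_i - y_i|, \quad
#'       MAPE = \frac{100}{M} \sum \frac{|\hat y_i - y_i|}{y_i},}
#' \deqn{RMSE = \sqrt{\frac1M \sum (\hat y_i - y_i)^2}, \quad
#'       R^2 = 1 - \frac{\sum(\hat y_i - y_i)^2}{\sum(\bar y - y_i)^2}.}
#' By default \eqn{\bar y} is the mean of the observed values (the standard
#' coefficient of determination); `r2_baseline = "predicted"` uses the mean
#' of the predictions instead, for compatibility with sources that define it
#' that way.
#'
#' @param y_true Observed values (strictly positive; MAPE divides by them).
#' @param y_pred Predicted values, same length.
#' @param r2_baseline `"observed"` (default) or `"predicted"`.
#' @return One-row tibble with `mae`, `mape` (percent), `rmse`, `r2`.
#' @examples
#' evaluate_predictions(c(100, 120), c(110, 110))
#' @export
evaluate_predictions <- function(y_true, y_pred,
                                 r2_baseline = c("observed", "predicted")) {
  r2_baseline <- match.arg(r2_baseline)
  if (length(y_true) != length(y_pred) || length(y_true) == 0)
    stop("`y_true` and `y_pred` must have equal, nonzero length", call. = FALSE)
  if (any(y_true == 0)) stop("MAPE undefined: `y_true` contains zeros", call. = FALSE)
  err <- y_pred - y_true
  ybar <- if (r2_baseline == "observed") mean(y_true) else mean(y_pred)
  ss_res <- sum(err^2)
  ss_tot <- sum((ybar - y_true)^2)
  tibble::tibble(
    mae = mean(abs(err)),
    mape = 100 * mean(abs(err) / abs(y_true)),
    rmse = sqrt(mean(err^2)),
    r2 = 1 - ss_res / ss_tot
  )
}

#' Grid search with k-fold cross-validation
#'
#' Exhaustive evaluation of a hyperparameter grid by mean k-fold validation
#' RMSE on the supplied (training) rows only; ties keep the first grid
#' entry.
#'
#' @param x,y Training features and weights.
#' @param method Registry method name (see [fit_regressor()]).
#' @param grid List of named hyperparameter lists (or a data frame, one row
#'   per configuration).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and fits.
#' @return List with `best_params`, `best_rmse` and a `results` tibble
#'   (one row per configuration).
#' @export
grid_search_cv <- function(x, y, method, grid, k = 5, seed = 1) {
  if (is.data.frame(grid)) grid <- lapply(seq_len(nrow(grid)),
                                          function(i) as.list(grid[i, ]))
  if (length(grid) == 0) stop("`grid` is empty", call. = FALSE)
  X <- check_xy(x, y)
  folds <- make_folds(nrow(X), k, seed)
  rmse <- vapply(grid, function(p) {
    fold_rmse <- vapply(seq_len(k), function(f) {
      tr <- which(folds != f)
      te <- which(folds == f)
      m <- fit_regressor(X[tr, , drop = FALSE], y[tr], method, params = p,
                         seed = seed)
      sqrt(mean((predict(m, X[te, , drop = FALSE]) - y[te])^2))
    }, numeric(1))
    mean(fold_rmse)
  }, numeric(1))
  best <- which.min(rmse) # first minimum: ties keep grid order
  list(best_params = grid[[best]], best_rmse = rmse[best],
       results = tibble::tibble(config = seq_along(grid), cv_rmse = rmse))
}

#' Pearson correlation screen of features against weight
#'
#' @param features Tibble/data frame of numeric feature columns (one row per
#'   frame).
#' @param weights Numeric weights (kg), one per row.
#' @return Tibble with columns `feature` and `r`. Zero-variance features get
#'   `NA` with a warning rather than a silent value.
#' @export
pearson_screen <- function(features, weights) {
  X <- as_feature_matrix(features)
  if (nrow(X) < 3) stop("need at least 3 rows", call. = FALSE)
  if (nrow(X) != length(weights)) stop("row counts differ", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  r <- rep(NA_real_, ncol(X))
  ok <- sds > 0 & stats::sd(weights) > 0
  r[ok] <- apply(X[, ok, drop = FALSE], 2, stats::cor, y = weights)
  if (any(!ok))
    warning("zero-variance columns have undefined correlation: ",
            paste(colnames(X)[!ok], collapse = ", "), call. = FALSE)
  tibble::tibble(feature = colnames(X) %||% paste0("V", seq_len(ncol(X))), r = r)
}
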