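#' Extract features from rendered scenes or mask files
#'
#' Streams frames through the cleanup chain ([clean_mask()]) and
#' [extract_features()], one frame in memory at a time.
#'
#' `extract_features_plan()` renders a [simulate_frames()] plan;
#' `extract_features_dir()` reads mask PNGs listed in a directory (frame ids
#' taken from filenames, pig ids from the `<pig>_f<frame>` prefix when
#' present).
#'
#' @param plan A `pigwt_plan` from [simulate_frames()].
#' @param kernel_size Opening element diameter (default 70).
#' @param clean Apply the cleanup chain before extraction (default `TRUE`;
#'   synthetic masks are clean already, but the full pipeline mirrors the
#'   mask-processing stage).
#' @return A tibble: `frame_id`, `pig_id`, the six feature columns, and for
#'   synthetic plans the ground-truth columns `bend_curvature`, `hdep_cm`,
#'   `pixels_per_cm`.
#' @export
extract_features_plan <- function(plan, kernel_size = 70, clean = TRUE) {
  rows <- vector("list", nrow(plan$frames))
  ds <- render_plan(plan, handler = function(sc, row) {
    mask <- if (clean) clean_mask(sc$mask, kernel_size = kernel_size) else sc$mask
    rows[[which(plan$frames$frame_id == row$frame_id)]] <<-
      dplyr::bind_cols(row[, c("frame_id", "pig_id", "bend_curvature")],
                       extract_features(mask))
  })
  feats <- dplyr::bind_rows(rows)
  dplyr::left_join(feats,
                   ds$frames[, c("frame_id", "hdep_cm", "pixels_per_cm")],
                   by = "frame_id")
}

#' @rdname extract_features_plan
#' @param masks_dir Directory of mask PNGs.
#' @param threshold Binarization threshold (default 0).
#' @export
extract_features_dir <- function(masks_dir, threshold = 0, kernel_size = 70) {
  files <- sort(list.files(masks_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG masks found in ", masks_dir, call. = FALSE)
  purrr::map_dfr(files, function(f) {
    frame_id <- sub("\\.png$", "", basename(f))
    pig_id <- sub("_f[0-9]+$", "", frame_id)
    mask <- clean_mask(read_mask_png(f), threshold = threshold,
                       kernel_size = kernel_size)
    dplyr::bind_cols(tibble::tibble(frame_id = frame_id, pig_id = pig_id),
                     extract_features(mask))
  })
}

#' Run the full weight-estimation pipeline
#'
#' Executes the complete chain on a synthetic herd (or pre-extracted
#' features): feature extraction, 7:3 split, feature correction trained on
#' the training split, strategy assembly, optional grid-search CV, model
#' fitting and test-set evaluation for every requested (strategy, method)
#' pair, plus the Pearson feature screen.
#'
#' @param config Named list. Recognized entries (all optional):
#'   `n_pigs` (39), `frames_per_pig` (39), `seed` (1), `camera`
#'   ([camera_config()]), `population` ([pig_population()]), `curvature_sd`
#'   (0.004), `boundary_noise` (0.015), `strategies` (`c("1", "2")`),
#'   `methods` (`c("XGBoost", "RFR")`), `split_mode` (`"frame"`),
#'   `split_ratio` (0.7), `kernel_size` (70), `grids` (named list
#'   `method -> grid` for [grid_search_cv()]), `params` (named list
#'   `method -> hyperparameters`), `features` (pre-extracted feature tibble,
#'   skips simulation), `biometry` (required with `features`).
#' @return An object of class `pigwt_report`: list with `metrics` (one row
#'   per strategy x method), `correlations`, `predictions` (per test frame),
#'   `correction` (fitted model and its BL/HW quality on test frames),
#'   `split`, `features`, `config`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(n_pigs = 6, frames_per_pig = 3,
#'                          methods = "LR", strategies = "1"))
#' rep$metrics
#' }
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(
    list(n_pigs = 39, frames_per_pig = 39, seed = 1,
         camera = camera_config(), population = pig_population(),
         curvature_sd = 0.004, boundary_noise = 0.015,
         strategies = c("1", "2"), methods = c("XGBoost", "RFR"),
         split_mode = "frame", split_ratio = 0.7, kernel_size = 70,
         grids = list(), params = list(), features = NULL, biometry = NULL,
         r2_baseline = "observed"),
    config
  )
  seeds <- child_seeds(cfg$seed, 4L)

  if (is.null(cfg$features)) {
    plan <- simulate_frames(cfg$n_pigs, cfg$frames_per_pig, cfg$population,
                            cfg$camera, cfg$curvature_sd, cfg$boundary_noise,
                            seed = cfg$seed)
    features <- extract_features_plan(plan, kernel_size = cfg$kernel_size)
    biometry <- plan$biometry
  } else {
    features <- cfg$features
    biometry <- cfg$biometry
    if (is.null(biometry)) stop("`biometry` is required with `features`", call. = FALSE)
  }

  n <- nrow(features)
  ds1 <- build_strategy_dataset(features, biometry, strategy = "1")
  split <- split_frames(ds1, ratio = cfg$split_ratio, mode = cfg$split_mode,
                        seed = seeds[1])

  needs_corr <- any(cfg$strategies %in% c("2", "3"))
  corrected <- NULL
  correction <- NULL
  if (needs_corr) {
    correction <- fit_correction(features[split$train, , drop = FALSE],
                                 biometry, camera = cfg$camera,
                                 seed = seeds[2])
    corrected <- apply_correction(correction, features)
    # training frames get out-of-fold corrections so the weight model trains
    # on corrected features with the same error profile it will see on test
    # frames (the full-split model would correct its own training frames
    # near-perfectly)
    k <- 5
    folds <- make_folds(length(split$train), k, seeds[2])
    for (fl in seq_len(k)) {
      tr_idx <- split$train[folds != fl]
      te_idx <- split$train[folds == fl]
      cm_f <- fit_correction(features[tr_idx, , drop = FALSE], biometry,
                             camera = cfg$camera, seed = seeds[2])
      co_f <- apply_correction(cm_f, features[te_idx, , drop = FALSE])
      corrected[match(features$frame_id[te_idx], corrected$frame_id),
                c("bl_hat_cm", "hw_hat_cm", "hdep_hat_cm")] <-
        co_f[, c("bl_hat_cm", "hw_hat_cm", "hdep_hat_cm")]
    }
  }

  metrics <- list()
  predictions <- list()
  for (st in cfg$strategies) {
    ds <- build_strategy_dataset(features, biometry, corrected, strategy = st)
    xtr <- ds$x[split$train, , drop = FALSE]
    ytr <- ds$y[split$train]
    xte <- ds$x[split$test, , drop = FALSE]
    yte <- ds$y[split$test]
    for (me in cfg$methods) {
      params <- cfg$params[[me]] %||% list()
      if (!is.null(cfg$grids[[me]])) {
        gs <- grid_search_cv(xtr, ytr, me, cfg$grids[[me]], k = 5,
                             seed = seeds[3])
        params <- utils::modifyList(params, gs$best_params)
      }
      model <- fit_regressor(xtr, ytr, me, params = params, seed = seeds[4])
      pred <- predict(model, xte)
      metrics[[length(metrics) + 1]] <- dplyr::bind_cols(
        tibble::tibble(strategy = st, method = me),
        evaluate_predictions(yte, pred, r2_baseline = cfg$r2_baseline)
      )
      predictions[[length(predictions) + 1]] <- tibble::tibble(
        strategy = st, method = me, frame_id = ds$frame_id[split$test],
        pig_id = ds$pig_id[split$test], weight_kg = yte, predicted_kg = pred
      )
    }
  }

  screen <- pearson_screen(
    features[, c("area_px2", "per_px", "pbl_px", "phw_px", "ecc", "dev")],
    dplyr::left_join(features, biometry[, c("pig_id", "weight_kg")],
                     by = "pig_id")$weight_kg
  )

  correction_quality <- NULL
  if (needs_corr && all(c("hdep_cm", "pixels_per_cm") %in% names(features))) {
    te <- split$test
    truth <- dplyr::left_join(features[te, ], biometry, by = "pig_id")
    corr_te <- corrected[te, ]
    naive_bl <- features$pbl_px[te] / features$pixels_per_cm[te]
    correction_quality <- tibble::tibble(
      bl_mae_corrected_cm = mean(abs(corr_te$bl_hat_cm - truth$body_length_cm)),
      bl_mae_naive_cm = mean(abs(naive_bl - truth$body_length_cm)),
      hw_mae_corrected_cm = mean(abs(corr_te$hw_hat_cm - truth$hip_width_cm)),
      hdep_mae_cm = mean(abs(corr_te$hdep_hat_cm - truth$hdep_cm))
    )
  }

  structure(
    list(metrics = dplyr::bind_rows(metrics),
         predictions = dplyr::bind_rows(predictions),
         correlations = screen,
         correction = correction,
         correction_quality = correction_quality,
         split = split, features = features, biometry = biometry,
         config = cfg),
    class = "pigwt_report"
  )
}

#' @export
print.pigwt_report <- function(x, ...) {
  cat(sprintf("<pigwt_report> %d frames (%d train / %d test, by %s)\n",
              nrow(x$features), length(x$split$train), length(x$split$test),
              x$split$mode))
  print(x$metrics)
  invisible(x)
}
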