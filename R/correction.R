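#' Camera-to-back distance of a pig
#'
#' The depth feature: with the camera mounted `hg` cm above the ground and a
#' pig of body height `hb` and hip height `hh`, the distance from the camera
#' to the pig's back is
#' \deqn{H_{dep} = H_g - \frac{H_b + H_h}{2}.}
#'
#' @param hg Camera height above ground (cm).
#' @param hb Body height (cm).
#' @param hh Hip height (cm).
#' @return Distance in cm (vectorized).
#' @examples
#' hdep_actual(145, 69.4, 75.13) # 72.735
#' @export
hdep_actual <- function(hg, hb, hh) {
  out <- hg - (hb + hh) / 2
  if (any(out <= 0))
    stop("camera is at or below the pig's back: hg must exceed (hb + hh)/2",
         call. = FALSE)
  out
}

#' Fit the feature-correction model
#'
#' Body bending shortens the apparent (projected) body length, so the raw
#' pixel features are biased. This stage learns, with Newton-boosted trees,
#' the map from image features to the measured body length and hip width and
#' to the camera-to-back distance [hdep_actual()], one booster per target.
#' The boosted estimates replace the raw pixel features downstream
#' (strategies 2 and 3).
#'
#' By default the correction inputs are the image features `pbl_px`,
#' `phw_px` and `dev` only, so the model can be applied to frames for which
#' no measured heights exist. Setting `include_hdep_input = TRUE` adds the
#' per-pig measured depth to the inputs, for setups where heights are also
#' measured at inference time.
#'
#' @param features Tibble of per-frame features with a `pig_id` column
#'   (output of the extraction stage).
#' @param biometry Tibble of per-pig measurements ([sample_biometry()]
#'   layout).
#' @param camera A [camera_config()]; supplies the camera height for the
#'   depth target.
#' @param inputs Character vector of feature columns used as inputs.
#' @param include_hdep_input Add measured `hdep` to the inputs (see above).
#' @param hyperparams Named list forwarded to [fit_gboost()].
#' @param seed Integer seed.
#' @return An object of class `pigwt_correction` holding the three fitted
#'   boosters, the input feature list and the training metadata.
#' @export
fit_correction <- function(features, biometry, camera = camera_config(),
                           inputs = c("pbl_px", "phw_px", "dev"),
                           include_hdep_input = FALSE,
                           hyperparams = list(), seed = 1) {
  if (!"pig_id" %in% names(features))
    stop("`features` needs a `pig_id` column", call. = FALSE)
  orphans <- setdiff(unique(features$pig_id), biometry$pig_id)
  if (length(orphans) > 0)
    stop("frames reference pigs absent from `biometry`: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  if (length(unique(features$pig_id)) < 2)
    stop("correction needs frames from at least 2 distinct pigs", call. = FALSE)
  joined <- dplyr::left_join(features, biometry, by = "pig_id")
  joined$hdep_cm_actual <- hdep_actual(camera$height_cm,
                                       joined$body_height_cm,
                                       joined$hip_height_cm)
  if (include_hdep_input) inputs <- union(inputs, "hdep_cm_actual")
  missing_in <- setdiff(inputs, names(joined))
  if (length(missing_in) > 0)
    stop("missing input columns: ", paste(missing_in, collapse = ", "), call. = FALSE)
  X <- joined[, inputs, drop = FALSE]
  hp <- utils::modifyList(list(rounds = 300, shrinkage = 0.1, lambda = 1,
                               gamma = 0, max_depth = 4), hyperparams)
  seeds <- child_seeds(seed, 3L)
  fit1 <- function(target, s)
    do.call(fit_gboost, c(list(x = X, y = joined[[target]], seed = s), hp))
  structure(
    list(model_bl = fit1("body_length_cm", seeds[1]),
         model_hw = fit1("hip_width_cm", seeds[2]),
         model_hdep = fit1("hdep_cm_actual", seeds[3]),
         inputs = inputs, hyperparams = hp, seed = seed,
         camera_height_cm = camera$height_cm),
    class = "pigwt_correction"
  )
}

#' Apply a feature-correction model
#'
#' @param model A [fit_correction()] object.
#' @param features Tibble of per-frame features containing the model's input
#'   columns (and optionally `frame_id`, carried through).
#' @return Tibble with columns `bl_hat_cm`, `hw_hat_cm`, `hdep_hat_cm` (plus
#'   `frame_id` / `pig_id` when present in `features`). Warns if any frame
#'   gets `bl_hat <= hw_hat`, which no plausible pig should.
#' @export
apply_correction <- function(model, features) {
  stopifnot(inherits(model, "pigwt_correction"))
  missing_in <- setdiff(model$inputs, names(features))
  if (length(missing_in) > 0)
    stop("features are missing the model's inputs: ",
         paste(missing_in, collapse = ", "), call. = FALSE)
  X <- features[, model$inputs, drop = FALSE]
  out <- tibble::tibble(
    bl_hat_cm = predict(model$model_bl, X),
    hw_hat_cm = predict(model$model_hw, X),
    hdep_hat_cm = predict(model$model_hdep, X)
  )
  if (any(out$bl_hat_cm <= out$hw_hat_cm))
    warning("some corrected frames have bl_hat <= hw_hat; implausible pig geometry",
            call. = FALSE)
  keep <- intersect(c("frame_id", "pig_id"), names(features))
  if (length(keep) > 0) out <- dplyr::bind_cols(features[, keep, drop = FALSE], out)
  out
}

#' @export
print.pigwt_correction <- function(x, ...) {
  cat(sprintf("<pigwt_correction> inputs: %s; targets: BL, HW, Hdep; %d rounds\n",
              paste(x$inputs, collapse = ", "), x$hyperparams$rounds))
  invisible(x)
}
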