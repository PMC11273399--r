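#' Plot a binary mask or rendered scene
#'
#' @param x Logical mask matrix or a `pigwt_scene`.
#' @param contour Optionally overlay a contour tibble from
#'   [extract_contour()].
#' @return A ggplot object.
#' @export
plot_mask <- function(x, contour = NULL) {
  mask <- if (inherits(x, "pigwt_scene")) x$mask else x
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  df <- tibble::tibble(row = idx[, 1], col = idx[, 2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = "grey20") +
    ggplot2::scale_y_reverse(limits = c(nrow(mask), 1)) +
    ggplot2::coord_fixed(xlim = c(1, ncol(mask))) +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(contour))
    p <- p + ggplot2::geom_path(data = contour, colour = "red", linewidth = 0.3)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods for pipeline results
#'
#' `autoplot.pigwt_report()` draws the per-method metric bars (one panel per
#' metric, colour per strategy, mirroring the usual strategy-comparison bar
#' charts); `plot_predictions()` draws the predicted-versus-true weight
#' scatter for selected strategy/method cells.
#'
#' @param object A `pigwt_report`.
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pigwt_report
#' @export
autoplot.pigwt_report <- function(object, metrics = c("mae", "mape", "rmse", "r2"),
                                  ...) {
  long <- tidyr::pivot_longer(object$metrics, cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "strategy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.pigwt_report
#' @param strategy,method Optional filters for the scatter.
#' @export
plot_predictions <- function(object, strategy = NULL, method = NULL) {
  df <- object$predictions
  if (!is.null(strategy)) df <- df[df$strategy %in% strategy, ]
  if (!is.null(method)) df <- df[df$method %in% method, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight_kg, y = .data$predicted_kg)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_grid(strategy ~ method) +
    ggplot2::labs(x = "measured weight (kg)", y = "predicted weight (kg)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pigwt_report
#' @export
plot_correlations <- function(object) {
  df <- if (inherits(object, "pigwt_report")) object$correlations else object
  df$feature <- factor(df$feature, levels = df$feature[order(df$r)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$r,
                                   fill = .data$r > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Pearson r with weight") +
    ggplot2::theme_minimal()
}
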