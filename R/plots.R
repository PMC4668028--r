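#' Plot a detection trade-off curve
#'
#' ROC curves are drawn as sensitivity against the false positive rate,
#' precision-recall as precision against recall, FROC as cluster
#' sensitivity against false positive clusters per image.
#'
#' @param object An `mc_curve` from [roc_curve()], [pr_curve()] or
#'   [froc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_curve <- function(object, ...) {
  type <- attr(object, "curve_type")
  map <- switch(type,
    roc = ggplot2::aes(.data$one_minus_specificity, .data$sensitivity),
    pr = ggplot2::aes(.data$sensitivity, .data$precision),
    froc = ggplot2::aes(.data$fp_per_image, .data$sensitivity)
  )
  labs <- switch(type,
    roc = ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                        title = "ROC"),
    pr = ggplot2::labs(x = "recall", y = "precision",
                       title = "Precision-recall"),
    froc = ggplot2::labs(x = "false positive clusters / image",
                         y = "cluster sensitivity", title = "FROC")
  )
  ggplot2::ggplot(object, map) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    labs +
    ggplot2::theme_minimal()
}

#' @export
plot.mc_curve <- function(x, ...) print(autoplot(x, ...))

mammogram_raster_df <- function(image) {
  px <- image$pixels
  tibble::tibble(
    row = rep(seq_len(nrow(px)) - 1, times = ncol(px)),
    col = rep(seq_len(ncol(px)) - 1, each = nrow(px)),
    intensity = as.vector(px)
  )
}

#' Plot a phantom with its ground truth
#'
#' @param phantom A phantom from [generate_phantom()].
#' @param show_truth Overlay planted microcalcifications and cluster boxes.
#' @return A ggplot (image in radiological orientation, row 0 on top).
#' @export
plot_phantom <- function(phantom, show_truth = TRUE) {
  p <- ggplot2::ggplot(mammogram_raster_df(phantom$image),
                       ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_truth && nrow(phantom$mc_points) > 0) {
    p <- p + ggplot2::geom_point(
      data = phantom$mc_points, shape = 1, colour = "red", size = 2)
  }
  if (show_truth && nrow(phantom$clusters) > 0) {
    p <- p + ggplot2::geom_rect(
      data = phantom$clusters,
      ggplot2::aes(xmin = .data$col_a, xmax = .data$col_b,
                   ymin = .data$row_a, ymax = .data$row_b),
      inherit.aes = FALSE, fill = NA, colour = "yellow")
  }
  p
}

#' Plot detections over a mammogram
#'
#' @param image A [mammogram_image()].
#' @param detections Detection tibble (0-based `row`, `col`).
#' @param truth Optional truth point tibble, drawn as open circles.
#' @return A ggplot.
#' @export
plot_detections <- function(image, detections, truth = NULL) {
  p <- ggplot2::ggplot(mammogram_raster_df(image),
                       ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_point(data = truth, shape = 1,
                                 colour = "yellow", size = 3)
  }
  if (nrow(detections) > 0) {
    p <- p + ggplot2::geom_point(data = detections, shape = 3,
                                 colour = "red", size = 2)
  }
  p
}
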