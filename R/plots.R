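#' Plot a repeat profile as a fragment-analysis trace
#'
#' Height-vs-repeat needle plot of one or more profiles, faceted by sample,
#' with an optional reference-mode guide line — the standard way these
#' capillary profiles are inspected.
#'
#' @param peaks Peak tibble (optionally multi-sample).
#' @param ref_mode Optional reference modal repeat drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_profile <- function(peaks, ref_mode = NULL) {
  check_columns(peaks, c("repeat_count", "height"), "profile")
  p <- ggplot2::ggplot(peaks,
    ggplot2::aes(x = .data$repeat_count, y = .data$height)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$repeat_count,
      yend = 0), linewidth = 0.4) +
    ggplot2::labs(x = "CAG repeat length", y = "Peak height") +
    ggplot2::theme_minimal()
  if (!is.null(ref_mode)) {
    p <- p + ggplot2::geom_vline(xintercept = ref_mode,
      linetype = "dashed", colour = "grey40")
  }
  if ("sample_id" %in% names(peaks) &&
      dplyr::n_distinct(peaks$sample_id) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$sample_id),
      scales = "free_y")
  }
  p
}

#' @describeIn pca_summary_stats Scores plot (samples on PC1/PC2, coloured
#'   by a label column when present) or loadings plot.
#' @param object A `repeat_pca` object.
#' @param type `"scores"` or `"loadings"`.
#' @export
autoplot.repeat_pca <- function(object, type = c("scores", "loadings"),
                                ...) {
  type <- match.arg(type)
  ve <- 100 * object$var_explained
  labs <- ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", ve[1L]),
    y = sprintf("PC2 (%.1f%%)", ve[2L]))
  if (type == "scores") {
    d <- object$scores
    aes <- if ("genotype" %in% names(d)) {
      ggplot2::aes(x = .data$PC1, y = .data$PC2,
        colour = .data$genotype,
        shape = if ("tissue" %in% names(d)) .data$tissue else NULL)
    } else {
      ggplot2::aes(x = .data$PC1, y = .data$PC2)
    }
    ggplot2::ggplot(d, aes) +
      ggplot2::geom_point(size = 2) +
      labs + ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$loadings,
      ggplot2::aes(x = .data$PC1, y = .data$PC2,
        label = .data$variable)) +
      ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0),
        colour = "grey60") +
      ggplot2::geom_text(size = 3) +
      labs + ggplot2::theme_minimal()
  }
}

#' @describeIn ancova_least_squares Least-squares means with confidence
#'   intervals per genotype.
#' @param object A `repeat_ancova` object.
#' @export
autoplot.repeat_ancova <- function(object, ...) {
  ggplot2::ggplot(ls_means(object),
    ggplot2::aes(x = .data$genotype, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
      ymax = .data$conf_high)) +
    ggplot2::labs(y = sprintf("%s (least-squares mean%s)", object$response,
      if (object$log_transform) ", geometric" else ""),
      x = object$genotype) +
    ggplot2::theme_minimal()
}

#' @describeIn rescue_analysis Histogram of alpha estimates with the
#'   reversal-class bands shaded.
#' @param object A `rescue_analysis` object.
#' @export
autoplot.rescue_analysis <- function(object, ...) {
  cuts <- object$params$thresholds
  rec <- dplyr::filter(object$records, .data$evaluable)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$alpha)) +
    ggplot2::geom_vline(xintercept = cuts, linetype = "dashed",
      colour = "grey50") +
    ggplot2::geom_histogram(bins = 60, fill = "grey30") +
    ggplot2::coord_cartesian(xlim = c(min(cuts) - 1, max(cuts) + 1)) +
    ggplot2::labs(x = expression(alpha ~ "(knockout effect / disease effect)"),
      y = "genes") +
    ggplot2::theme_minimal()
}

#' @describeIn segment_objects Raster of the image with retained-object
#'   centroids marked.
#' @param object A `segmentation_result`.
#' @param image Optional original image matrix to draw under the objects.
#' @export
autoplot.segmentation_result <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    d <- tibble::tibble(
      row = as.vector(row(image)), col = as.vector(col(image)),
      value = as.vector(image))
    p <- p + ggplot2::geom_raster(data = d,
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
        limits = c(0, 255))
  }
  p +
    ggplot2::geom_point(data = object$objects,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row,
        size = .data$area), colour = "red", shape = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
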