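#' Plot an MDS map with its convex hull
#'
#' Scatter of the first two embedding dimensions with the convex hull around
#' all points, the way representation spaces are usually displayed.
#'
#' @param object An `attn_mds`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.attn_mds <- function(object, ...) {
  df <- tidy(object)
  hull <- df[chull(df$dim1, df$dim2), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::geom_polygon(data = hull, fill = NA, colour = "grey50",
                          linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stimulus),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2")
}

#' Plot a bootstrap null distribution
#'
#' Histogram of the shuffle-split null stresses with the observed stress
#' marked.
#'
#' @param object An `attn_boot`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.attn_boot <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$null_stress)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_stress, colour = "red") +
    ggplot2::labs(x = "stress under shuffle-split null", y = "count",
                  subtitle = sprintf("observed %.3f, p = %.3f",
                                     object$observed_stress, object$p_value))
}

#' Histograms of attentional gain factors
#'
#' Gain-factor distributions per area and decode space, colored by attention
#' task, with unity marked.
#'
#' @param gains Tibble from [estimate_gains()].
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_gain_histograms <- function(gains, bins = 25) {
  ggplot2::ggplot(gains, ggplot2::aes(.data$gain, fill = .data$task)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::facet_grid(area ~ decode_space) +
    ggplot2::labs(x = "attentional gain factor", y = "cells")
}

#' Aligned MDS maps for two conditions
#'
#' Procrustes-aligns the second condition's map to the first and overlays the
#' two, with arrows linking corresponding stimuli.
#'
#' @param report An `attn_report` from [run_full_analysis()].
#' @param area,decode_space Which population and space.
#' @param cond_a,cond_b Condition labels (see `report_conditions`).
#' @param allow_scaling Scaling aspect of the alignment.
#' @return A ggplot.
#' @export
plot_aligned_maps <- function(report, area, decode_space,
                              cond_a = "shape_attention",
                              cond_b = "location_attention",
                              allow_scaling = TRUE) {
  A <- report$embeddings[[paste(area, decode_space, cond_a, sep = ".")]]
  B <- report$embeddings[[paste(area, decode_space, cond_b, sep = ".")]]
  al <- procrustes_align(A$points[, 1:2], B$points[, 1:2], allow_scaling)
  df <- dplyr::bind_rows(
    dplyr::mutate(tidy(A), condition = cond_a),
    dplyr::mutate(tibble::tibble(stimulus = B$labels,
                                 dim1 = al$Yaligned[, 1],
                                 dim2 = al$Yaligned[, 2]),
                  condition = cond_b)
  )
  seg <- tibble::tibble(
    x = A$points[, 1], y = A$points[, 2],
    xend = al$Yaligned[, 1], yend = al$Yaligned[, 2]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2, colour = .data$condition)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          inherit.aes = FALSE, colour = "grey70",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  subtitle = sprintf("stress %.4f", al$stress))
}
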