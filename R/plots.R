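#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pileup matrix
#'
#' Heatmap of the averaged O/E (log2 colour scale), centre marked for point
#' pileups.
#'
#' @param object an `hic_pileup`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hic_pileup
#' @export
autoplot.hic_pileup <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = log2(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "log2 O/E") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("%s pileup (%d %s)",
                      if (object$rescaled) "Rescaled local" else "Distal",
                      object$n_pairs,
                      if (object$rescaled) "regions" else "pairs"),
      subtitle = if (!is.na(object$condition)) object$condition else NULL) +
    ggplot2::theme_minimal()
}

#' Plot compaction by occupancy group
#'
#' Group means of intra-window O/E totals with 95% confidence intervals.
#'
#' @param object a `compaction_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot compaction_result
#' @export
autoplot.compaction_result <- function(object, ...) {
  ggplot2::ggplot(object$group_summary,
                  ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::labs(x = "occupancy group", y = "mean intra-window O/E total",
                  title = object$condition) +
    ggplot2::theme_minimal()
}

#' Plot FISH interprobe distances by condition
#'
#' Violin plot with the colocalization threshold marked.
#'
#' @param fish FISH table (e.g. from [simulate_fish()], possibly row-bound
#'   across conditions).
#' @param distance which distance column to show.
#' @param threshold colocalization threshold line (micrometres).
#' @return a ggplot.
#' @export
plot_fish_distances <- function(fish, distance = "d12", threshold = 0.2) {
  ggplot2::ggplot(fish, ggplot2::aes(.data$condition, .data[[distance]])) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = sprintf("%s (µm)", distance)) +
    ggplot2::theme_minimal()
}

#' Plot clustering-category percentages per condition
#'
#' @param object a `clustering_test`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot clustering_test
#' @export
autoplot.clustering_test <- function(object, ...) {
  df <- as.data.frame(object$percentages)
  names(df) <- c("condition", "category", "percent")
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$percent,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% nuclei",
                  subtitle = sprintf("chi-square p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}

#' Plot a contact-probability curve
#'
#' log-log P(s) with slope reference.
#'
#' @param curve output of [contact_probability_curve()].
#' @return a ggplot.
#' @export
plot_contact_decay <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$s_mid, .data$mean_contact)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic separation (bp)", y = "mean contact") +
    ggplot2::theme_minimal()
}
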