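# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_rect geom_segment facet_wrap labs position_dodge scale_y_continuous
#' @export
ggplot2::autoplot

#' Plot observed vs expected microhomology distribution
#'
#' Grouped bars of observed junction counts per microhomology length against
#' the random-joining expectation.
#'
#' @param object an `mh_enrichment` object from [mh_enrichment_test()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mh_enrichment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("observed", "expected"),
                              names_to = "which", values_to = "count")
  ggplot(long, aes(x = factor(.data$k), y = .data$count,
                   fill = .data$which)) +
    geom_col(position = position_dodge()) +
    labs(x = "microhomology length (bp)", y = "junctions", fill = NULL,
         title = sprintf("Microhomology at junctions: %.0f%% with mh ≥ 1 vs %.1f%% expected",
                         100 * object$estimate, 100 * object$null_p))
}

#' Plot a binned coverage profile
#'
#' Log2 mean depth per bin along each chromosome, with called amplified
#' segments overlaid if provided.
#'
#' @param bins a `coverage_bins` tibble from [bin_depth()].
#' @param segments optional called segments from
#'   [call_amplified_segments()].
#' @return a ggplot.
#' @export
plot_coverage <- function(bins, segments = NULL) {
  bins <- as_tibble(bins)
  p <- ggplot(bins, aes(x = (.data$start + .data$end) / 2e6,
                        y = .data$log2_depth)) +
    geom_point(size = 0.3, na.rm = TRUE) +
    facet_wrap(~chrom, scales = "free_x", ncol = 1) +
    labs(x = "position (Mb)", y = "log2 coverage")
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + geom_rect(
      data = as_tibble(segments),
      aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red",
      inherit.aes = FALSE)
  }
  p
}

#' Plot breakpoint clusters along a chromosome
#'
#' One tick per breakend, coloured by cluster membership.
#'
#' @param clustered output of [cluster_breakpoints()].
#' @return a ggplot.
#' @export
plot_breakpoint_clusters <- function(clustered) {
  b <- as_tibble(clustered)
  b$grouped <- ifelse(is.na(b$cluster), "singleton", b$cluster)
  ggplot(b, aes(x = .data$pos / 1e6, y = 0, colour = .data$grouped)) +
    geom_point(shape = "|", size = 5) +
    facet_wrap(~chrom, ncol = 1) +
    labs(x = "position (Mb)", y = NULL, colour = "cluster") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
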