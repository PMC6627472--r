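# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a methylation metaprofile
#'
#' @param object A `methdev_metaprofile` (or a row-bound tibble of several,
#'   e.g. one per stage with a `stage` column).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methdev_metaprofile <- function(object, ...) {
  colour <- if ("stage" %in% names(object)) "stage" else NULL
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$mean_level)) +
    ggplot2::geom_vline(
      xintercept = range(object$bin[object$zone == "body"]) + c(-0.5, 0.5),
      linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "bin (5' flank - body - 3' flank)", y = "mean mCG level") +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_line()
  } else {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$stage))
  }
}

#' Plot mCG level distribution (bimodality)
#'
#' Histogram of methylation levels among called mCGs; the two modes of a
#' fungal methylome (lowly methylated genic sites, highly methylated
#' TE/intergenic sites) show as peaks below 10% and above 70%.
#'
#' @param sites Called site tibble (with `is_mcg`).
#' @param bins Histogram bins (default 50).
#' @return A ggplot.
#' @export
plot_mcg_level_distribution <- function(sites, bins = 50) {
  ggplot2::ggplot(dplyr::filter(sites, .data$is_mcg),
                  ggplot2::aes(x = .data$level)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = NA) +
    ggplot2::labs(x = "mCG level", y = "mCG count") +
    ggplot2::theme_minimal()
}

#' Plot promoter-to-TE distance by methylation class
#'
#' @param te_dist Tibble from [distance_to_nearest_te()] with `mclass`.
#' @return A ggplot (boxplots on log10(distance + 1)).
#' @export
plot_te_distance <- function(te_dist) {
  te_dist$mclass <- factor(te_dist$mclass, levels = c("none", "low", "medium", "high"))
  ggplot2::ggplot(dplyr::filter(te_dist, !is.na(.data$dist_te)),
                  ggplot2::aes(x = .data$mclass, y = log10(.data$dist_te + 1))) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "promoter methylation class", y = "log10(distance to nearest TE + 1)") +
    ggplot2::theme_minimal()
}

#' Plot ortholog fold-change agreement for one phase
#'
#' @param divergence Tibble from [ortholog_divergence()].
#' @param phase Phase label.
#' @return A ggplot of species A vs species B log2 fold changes coloured by
#'   divergence class.
#' @export
plot_foldchange_scatter <- function(divergence, phase) {
  d <- dplyr::filter(divergence, .data$phase == !!phase)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc_a, y = .data$log2fc_b,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "log2 fold change (species A)",
                  y = "log2 fold change (species B)", colour = "class",
                  title = phase) +
    ggplot2::theme_minimal()
}
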