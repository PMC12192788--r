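#' Manhattan-style plot of per-SNP ROH incidence
#'
#' Plots the fraction of a population's individuals covered by a run at
#' each marker, ordered along the genome with chromosomes alternating
#' in shade, with the island-selection threshold as a dashed line.
#'
#' @param incidence Tibble from [snp_incidence()].
#' @param threshold Optional incidence threshold to draw (e.g. from
#'   [top_percentile_threshold()]).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_snp_incidence <- function(incidence, threshold = NULL, title = NULL) {
  inc <- incidence[order(chrom_sort_key(incidence$chrom), incidence$pos), ]
  inc$chrom <- factor(inc$chrom, levels = unique(inc$chrom))
  inc$x <- seq_len(nrow(inc))
  p <- ggplot2::ggplot(inc, ggplot2::aes(x = .data$x, y = .data$incidence,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = rep(c("grey30", "steelblue"),
                   length.out = nlevels(inc$chrom))) +
    ggplot2::labs(x = "SNP index (genome order)",
                  y = "ROH incidence", title = title) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Distribution of a genomic coefficient by population
#'
#' Boxplots of per-animal F_ROH (or D_ROHet) per population, faceted by
#' length class.
#'
#' @param coef_tbl Tibble from [f_roh()] or [d_rohet()].
#' @param value Column plotted, `"froh"` or `"drohet"`.
#' @return A ggplot object.
#' @export
plot_coefficient <- function(coef_tbl, value = c("froh", "drohet")) {
  value <- match.arg(value)
  lv <- unique(coef_tbl$class[order(coef_tbl$threshold_bp)])
  coef_tbl$class <- factor(coef_tbl$class, levels = lv)
  ggplot2::ggplot(coef_tbl,
                  ggplot2::aes(x = .data$population,
                               y = .data[[value]],
                               fill = .data$population)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = NULL, y = toupper(value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Mean run count or sum by length class and population
#'
#' Line plot of the per-population mean run statistic along the
#' cumulative threshold ladder, mirroring the layered per-breed decline
#' of counts and sums with increasing minimum length.
#'
#' @param pop_summary Tibble from [population_summary()].
#' @param what `"count"` or `"sum"`.
#' @return A ggplot object.
#' @export
plot_length_classes <- function(pop_summary, what = c("count", "sum")) {
  what <- match.arg(what)
  ycol <- if (what == "count") "mean_n_runs" else "mean_sum_mb"
  ggplot2::ggplot(pop_summary,
                  ggplot2::aes(x = .data$threshold_bp / 1e6,
                               y = .data[[ycol]],
                               colour = .data$population)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "minimum length (Mb)",
                  y = if (what == "count") "mean runs per animal"
                      else "mean summed length (Mb)",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of pairwise comparison p-values
#'
#' @param object A `breed_comparison` from [pairwise_breed_tests()].
#' @param statistic Statistic to display (`"n_runs"` or `"sum_bp"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.breed_comparison <- function(object, statistic = "sum_bp", ...) {
  d <- object$results[object$results$statistic == statistic, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pop_a, y = .data$pop_b,
                                  fill = -log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
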