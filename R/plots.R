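#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-locus statistic histogram
#'
#' Bars are the half-open bins of [stat_histogram()]; the dashed line marks
#' the extreme-value threshold whose exceedance count is annotated.
#'
#' @param values Per-locus statistic values (`NA` allowed).
#' @param bin_width,extreme_threshold Passed to [stat_histogram()].
#' @param name Axis label for the statistic.
#' @return A ggplot.
#' @export
plot_stat_histogram <- function(values, bin_width = 0.05,
                                extreme_threshold = 0.975,
                                name = "statistic") {
  h <- stat_histogram(values, bin_width, extreme_threshold)
  ggplot2::ggplot(h$bins, ggplot2::aes(x = .data$bin_lo + bin_width / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey35") +
    ggplot2::geom_vline(xintercept = extreme_threshold, linetype = "dashed") +
    ggplot2::labs(
      x = name, y = "loci",
      subtitle = sprintf("%d loci > %.3f; %d undefined",
                         h$n_extreme, extreme_threshold, h$n_undefined)
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot methods for result objects
#'
#' `resampling_result`: replicate-value histogram with the point estimate
#' (solid) and percentile CI (dashed). `subsample_experiment`: per-size
#' replicate distributions against the full panel's estimate and CI.
#' `pca_result`: PC1/PC2 scores coloured by population. `dataset_family`:
#' locus count and missing-call percentage along the completeness gradient.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resampling_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$point_estimate, colour = "blue") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        colour = "blue", linetype = "dashed") +
    ggplot2::labs(x = object$statistic, y = "replicates") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.resampling_result
#' @export
autoplot.subsample_experiment <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$full$point_estimate,
                        colour = "blue") +
    ggplot2::geom_vline(xintercept = c(object$full$ci_low, object$full$ci_high),
                        colour = "blue", linetype = "dashed") +
    ggplot2::facet_wrap(~size, scales = "free_y") +
    ggplot2::labs(x = object$statistic, y = "samplings") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.resampling_result
#' @export
autoplot.pca_result <- function(object, ...) {
  pve <- 100 * object$explained_variance
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pve[1]),
                  y = sprintf("PC2 (%.1f%%)", pve[2])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.resampling_result
#' @export
autoplot.dataset_family <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary, c("n_loci", "pct_missing_cells"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "individuals required to retain a locus") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
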