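#' Replicate-vs-replicate scatter plots of a variability result
#'
#' One panel per sample: log2(FPKM + pseudocount) of replicate 2 against
#' replicate 1 for floor-passing genes, with called variable genes
#' highlighted and the Pearson correlation in the panel label.
#'
#' @param object A `variability_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variability_result
#' @export
autoplot.variability_result <- function(object, ...) {
  pc <- object$config$pseudocount
  d <- tidy(object)
  labels <- setNames(
    sprintf("%s  (r = %.3f)", object$correlations$sample,
            object$correlations$pearson_r),
    object$correlations$sample
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = log2(.data$fpkm_r1 + pc), y = log2(.data$fpkm_r2 + pc),
                 colour = .data$variable)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::facet_wrap(~sample, labeller = ggplot2::as_labeller(labels)) +
    ggplot2::labs(
      x = "replicate 1, log2(FPKM + 1)",
      y = "replicate 2, log2(FPKM + 1)",
      colour = "variable"
    ) +
    ggplot2::theme_minimal()
}

#' Frequency-distribution plot of a trait by line
#'
#' Histogram with fixed bin width per line, with the line median marked, the
#' standard way to display within-population growth variability.
#'
#' @param data Data frame with columns `line` and `value`.
#' @param bin_width Positive bin width in trait units.
#' @param origin Left edge of bin zero. Default 0.
#' @return A ggplot object.
#' @export
plot_trait_distribution <- function(data, bin_width, origin = 0) {
  if (!all(c("line", "value") %in% names(data))) {
    abort("`data` must have columns line and value")
  }
  check_positive_scalar(bin_width, "bin_width")
  medians <- data |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(median = median(.data$value), .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = bin_width,
                            boundary = origin,
                            closed = "left",
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = medians,
                        ggplot2::aes(xintercept = .data$median),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~line, ncol = 1) +
    ggplot2::labs(x = "trait value", y = "count") +
    ggplot2::theme_minimal()
}
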