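#' Plot the simulated ICC sampling distributions
#'
#' Relative-frequency histograms of the three single-score ICC estimators
#' over the simulation replicates, one panel per estimator, with the
#' empirical central range marked by dashed lines.
#'
#' @param object An `icc_sim` from [icc_simulate()].
#' @param bins Number of histogram channels (default 100).
#' @param range Numeric range covered by the channels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icc_sim <- function(object, bins = 100, range = c(-0.5, 1), ...) {
  hist_tbl <- dplyr::bind_rows(lapply(
    c("icc1", "icc_a1", "icc_c1"),
    function(col) {
      h <- icc_histogram(object$draws[[col]], bins = bins, range = range)
      h$statistic <- col
      h
    }
  ))
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(x = .data$bin_center, y = .data$rel_freq)) +
    ggplot2::geom_col(width = diff(range) / bins, fill = "steelblue") +
    ggplot2::geom_vline(
      data = object$central_ranges,
      mapping = ggplot2::aes(xintercept = .data$lower),
      linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(
      data = object$central_ranges,
      mapping = ggplot2::aes(xintercept = .data$upper),
      linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~statistic, ncol = 1) +
    ggplot2::labs(x = "sample ICC", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Plot central-range curves against the population ICC
#'
#' The two curves bound the central range of the sample ICC(1) distribution
#' at each population ICC; reading the figure horizontally at an observed
#' sample value gives the simulation-based confidence limits.
#'
#' @param object An `icc_conf_curve` from [icc_conf_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icc_conf_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("lower", "upper"),
                              names_to = "limit", values_to = "icc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rho, y = .data$icc,
                                     linetype = .data$limit)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "population ICC",
      y = sprintf("%g%% central range of sample ICC(1)",
                  100 * attr(object, "level"))) +
    ggplot2::theme_minimal()
}
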