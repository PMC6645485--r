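# JSON serialization of analysis and simulation results. Reports carry a
# schema_version field and stable key order so downstream consumers can
# round-trip them.

REPORT_SCHEMA_VERSION <- "1.0"

#' Convert an analysis or simulation result to a plain list
#'
#' @param x An `icc_fit` or `icc_sim`.
#' @param histograms For `icc_sim`, include per-estimator histograms
#'   (default `FALSE` to keep reports small).
#' @return A named list mirroring the JSON report layout.
#' @export
as_icc_report <- function(x, histograms = FALSE) {
  if (inherits(x, "icc_fit")) {
    list(
      schema_version = REPORT_SCHEMA_VERSION,
      kind = "analysis",
      n = x$n, k = x$k, alpha = x$alpha, level = x$level,
      anova = as.data.frame(x$anova),
      estimates = as.data.frame(x$estimates),
      ratio_c_over_a = x$ratio_c_over_a,
      bias_test = as.data.frame(x$bias_test),
      variance_components = list(
        oneway = as.data.frame(x$varcomp_oneway),
        twoway = as.data.frame(x$varcomp_twoway)
      ),
      conclusion = x$conclusion
    )
  } else if (inherits(x, "icc_sim")) {
    out <- list(
      schema_version = REPORT_SCHEMA_VERSION,
      kind = "simulation",
      params = x$params[c("model", "mu", "sigma_r", "sigma_v", "sigma_c",
                          "biases", "n", "k")],
      N = x$N, seed = x$seed, n_degenerate = x$n_degenerate,
      summary = as.data.frame(x$summary),
      central_ranges = as.data.frame(x$central_ranges),
      ratio = as.data.frame(x$ratio)
    )
    if (histograms) {
      out$histograms <- lapply(
        setNames(nm = c("icc1", "icc_a1", "icc_c1")),
        function(col) as.data.frame(icc_histogram(x$draws[[col]]))
      )
    }
    out
  } else {
    abort("as_icc_report() expects an icc_fit or icc_sim object")
  }
}

#' Write a JSON report
#'
#' Serializes an analysis or simulation result to JSON at full double
#' precision. The file round-trips losslessly through
#' [read_icc_report()].
#'
#' @inheritParams as_icc_report
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_icc_report <- function(x, path, histograms = FALSE) {
  rep <- as_icc_report(x, histograms = histograms)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path to a file written by [write_icc_report()].
#' @return The report as a named list of data frames and scalars.
#' @export
read_icc_report <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
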