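#' Model-agnostic ICC analysis of a reliability study
#'
#' Runs the full analysis recipe on a complete subjects-by-measurements
#' score matrix without committing to a generative model in advance:
#' computes the repeated-measures ANOVA, all three single-score ICCs with
#' confidence intervals, the ratio ICC(C,1)/ICC(A,1), the bias F-test, and
#' variance components under both the one-way and two-way solutions. The
#' conclusion is `"no_bias"` when the F-test is non-significant at `alpha`
#' — ICC(1) may then be reported alongside the other two — and
#' `"bias_present"` otherwise, in which case only ICC(A,1) and ICC(C,1) are
#' valid and flagged for reporting. The ratio is advisory: values within
#' `ratio_threshold` of 1 suggest negligible bias, but the F-test decides.
#'
#' @param data A data frame, matrix or `score_matrix`.
#' @param alpha Significance level of the bias F-test (default 0.05).
#' @param level Confidence level for the ICC intervals (default 0.95).
#' @param ci `"analytic"` (F-based formulas, default) or `"simulated"`
#'   (central-range inversion, applied to ICC(1) and ICC(C,1); ICC(A,1)
#'   keeps its analytic interval, which the simulated curves do not cover).
#' @param ratio_threshold Advisory cut-off on ICC(C,1)/ICC(A,1) (default
#'   1.02, i.e. "within a few percent of 1").
#' @param seed Seed for the simulated intervals, if requested.
#' @return An object of class `icc_fit`: a list with elements `anova`,
#'   `estimates` (tibble: `type`, `estimate`, `conf.low`, `conf.high`,
#'   `band`, `reportable`), `bias_test`, `varcomp_oneway`,
#'   `varcomp_twoway`, `ratio_c_over_a`, `conclusion`, `n`, `k`, `alpha`,
#'   `level`.
#' @examples
#' fit <- icc_analyze(emg_mf())
#' fit
#' tidy(fit)
#' glance(fit)
#' @export
icc_analyze <- function(data, alpha = 0.05, level = 0.95,
                        ci = c("analytic", "simulated"),
                        ratio_threshold = 1.02, seed = NULL) {
  ci <- match.arg(ci)
  an <- icc_anova(data)
  n <- attr(an, "n")
  k <- attr(an, "k")
  est <- icc_confint(an, level = level)
  if (ci == "simulated") {
    curve <- icc_conf_curve(n, k, level = level, seed = seed)
    for (tt in c("icc1", "icc_c1")) {
      i <- which(est$type == tt)
      if (est$estimate[i] < 1) {
        sci <- icc_confint_simulated(max(est$estimate[i], 0), n, k,
                                     level = level, curve = curve)
        est$conf.low[i] <- sci$conf.low
        est$conf.high[i] <- sci$conf.high
      }
    }
  }
  bt <- bias_f_test(an, alpha = alpha)
  conclusion <- if (bt$reject) "bias_present" else "no_bias"
  est$band <- icc_band(est$estimate)
  est$reportable <- est$type != "icc1" | conclusion == "no_bias"
  ia <- est$estimate[est$type == "icc_a1"]
  ic <- est$estimate[est$type == "icc_c1"]
  ratio <- if (ia != 0) ic / ia else NA_real_

  structure(
    list(
      anova = an,
      estimates = est,
      bias_test = bt,
      varcomp_oneway = variance_components(an, "oneway"),
      varcomp_twoway = variance_components(an, "twoway"),
      ratio_c_over_a = ratio,
      ratio_threshold = ratio_threshold,
      conclusion = conclusion,
      n = n, k = k, alpha = alpha, level = level, ci_method = ci
    ),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.icc_fit <- function(x, ...) {
  lab <- c(icc1 = "ICC(1)  ", icc_a1 = "ICC(A,1)", icc_c1 = "ICC(C,1)")
  lines <- c(
    sprintf("Single-score ICC analysis: %d subjects x %d measurements",
            x$n, x$k),
    "",
    vapply(seq_len(nrow(x$estimates)), function(i) {
      e <- x$estimates[i, ]
      sprintf("  %s %6.3f  (%d%% CI %.3f to %.3f)  [%s]%s",
              lab[[e$type]], e$estimate, round(100 * x$level),
              e$conf.low, e$conf.high, e$band,
              if (e$reportable) "" else "  <- not valid under bias")
    }, character(1)),
    "",
    sprintf("  ICC(C,1)/ICC(A,1) ratio: %.3f (advisory threshold %.2f)",
            x$ratio_c_over_a, x$ratio_threshold),
    sprintf("  Bias F-test: F(%d, %d) = %.3f, p = %.3f -> %s",
            x$bias_test$df1, x$bias_test$df2, x$bias_test$statistic,
            x$bias_test$p.value,
            if (x$conclusion == "no_bias") {
              "no significant bias between measurements"
            } else {
              "significant bias between measurements"
            }),
    "",
    sprintf("  One-way SDs: sigma_r = %.2f, sigma_v = %.2f",
            x$varcomp_oneway$sd[1], x$varcomp_oneway$sd[2]),
    sprintf("  Two-way SDs: sigma_r = %.2f, sigma_c = %.2f, sigma_v = %.2f",
            x$varcomp_twoway$sd[1], x$varcomp_twoway$sd[2],
            x$varcomp_twoway$sd[3])
  )
  lines
}

#' Tidy the ICC estimates of an analysis
#'
#' @param x An `icc_fit` from [icc_analyze()].
#' @param ... Unused.
#' @return The estimates tibble: one row per estimator with `type`,
#'   `estimate`, `conf.low`, `conf.high`, `band`, `reportable`.
#' @export
tidy.icc_fit <- function(x, ...) x$estimates

#' One-row summary of an ICC analysis
#'
#' @param x An `icc_fit` from [icc_analyze()].
#' @param ... Unused.
#' @return A one-row tibble: `n`, `k`, the three ICC estimates,
#'   `ratio_c_over_a`, `f_statistic`, `p.value`, `conclusion`.
#' @export
glance.icc_fit <- function(x, ...) {
  e <- setNames(x$estimates$estimate, x$estimates$type)
  tibble(
    n = x$n, k = x$k,
    icc1 = e[["icc1"]], icc_a1 = e[["icc_a1"]], icc_c1 = e[["icc_c1"]],
    ratio_c_over_a = x$ratio_c_over_a,
    f_statistic = x$bias_test$statistic,
    p.value = x$bias_test$p.value,
    conclusion = x$conclusion
  )
}
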