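# Single-score ICC estimators. All are ratios of the repeated-measures
# ANOVA mean squares; `anova` below may be an icc_anova tibble or the raw
# score matrix/data frame (coerced internally).

icc1_value <- function(ms) {
  den <- ms$msbs + (ms$k - 1) * ms$msws
  if (den <= 0) stop_degenerate("ICC(1) undefined: MSBS + (k-1)*MSWS is not positive (constant matrix?)")
  (ms$msbs - ms$msws) / den
}

icc_a1_value <- function(ms) {
  den <- ms$msbs + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msbm - ms$mse)
  if (den <= 0) stop_degenerate("ICC(A,1) undefined: denominator is not positive (constant matrix?)")
  (ms$msbs - ms$mse) / den
}

icc_c1_value <- function(ms) {
  den <- ms$msbs + (ms$k - 1) * ms$mse
  if (den <= 0) stop_degenerate("ICC(C,1) undefined: MSBS + (k-1)*MSE is not positive (constant matrix?)")
  (ms$msbs - ms$mse) / den
}

icc_a1_alt_value <- function(ms) {
  den <- ms$mswm - ms$mse + ms$msws
  if (den <= 0) stop_degenerate("alternative ICC(A,1) undefined: MSWM - MSE + MSWS is not positive")
  (ms$mswm - ms$mse) / den
}

#' One-way random-effects single-score ICC, ICC(1)
#'
#' `(MSBS - MSWS) / (MSBS + (k-1) MSWS)`. Valid only when there is no
#' systematic difference (bias) between measurements; negative estimates are
#' legitimate small-sample outcomes and are returned as-is. The smallest
#' attainable value is `-1/(k-1)`.
#'
#' @param anova An `icc_anova` table, or the score data to decompose.
#' @return A length-one double.
#' @examples
#' icc1(icc_anova(emg_mf()))
#' @export
icc1 <- function(anova) icc1_value(as_ms_list(anova))

#' Absolute-agreement single-score ICC, ICC(A,1)
#'
#' `(MSBS - MSE) / (MSBS + (k-1) MSE + (k/n)(MSBM - MSE))`. The bias
#' variance stays in the denominator, so systematic differences between
#' measurements lower the estimate. Valid under both the two-way random and
#' two-way mixed models.
#'
#' @inheritParams icc1
#' @return A length-one double.
#' @export
icc_a1 <- function(anova) icc_a1_value(as_ms_list(anova))

#' Consistency single-score ICC, ICC(C,1)
#'
#' `(MSBS - MSE) / (MSBS + (k-1) MSE)`. Bias variance is excluded: the
#' coefficient measures whether subjects keep their ranking and mutual
#' differences across measurements, and its sampling distribution is
#' unaffected by any additive per-measurement bias.
#'
#' @inheritParams icc1
#' @return A length-one double.
#' @export
icc_c1 <- function(anova) icc_c1_value(as_ms_list(anova))

#' Alternative algebraic form of ICC(A,1)
#'
#' `(MSWM - MSE) / (MSWM - MSE + MSWS)`, mathematically identical to
#' [icc_a1()] on every complete matrix. Exposed as an internal consistency
#' check of the ANOVA decomposition, not as a separate estimator.
#'
#' @inheritParams icc1
#' @return A length-one double, equal to `icc_a1(anova)` to rounding error.
#' @export
icc_a1_alt <- function(anova) icc_a1_alt_value(as_ms_list(anova))

#' Variance components from the ANOVA mean squares
#'
#' Solves the expected-mean-square relations for the subject variance
#' sigma_r^2, the noise variance sigma_v^2 and (two-way only) the bias
#' variance sigma_c^2:
#' one-way: `sigma_r^2 = (MSBS - MSWS)/k`, `sigma_v^2 = MSWS`;
#' two-way: `sigma_r^2 = (MSBS - MSE)/k`, `sigma_c^2 = (MSBM - MSE)/n`,
#' `sigma_v^2 = MSE`. Under the two-way mixed model the same `sigma_c^2`
#' expression estimates the fixed-bias spread theta_c^2. Negative estimates
#' are possible in small samples; they are flagged, never truncated, and
#' their standard deviation is reported as `NaN`.
#'
#' @inheritParams icc1
#' @param model `"oneway"` or `"twoway"`.
#' @return A tibble with columns `component` (`sigma_r`, `sigma_c`,
#'   `sigma_v`), `variance`, `sd` and `negative`.
#' @examples
#' variance_components(icc_anova(emg_mf()), "twoway")
#' @export
variance_components <- function(anova, model = c("twoway", "oneway")) {
  model <- match.arg(model)
  ms <- as_ms_list(anova)
  if (model == "oneway") {
    v <- c(sigma_r = (ms$msbs - ms$msws) / ms$k, sigma_v = ms$msws)
  } else {
    v <- c(sigma_r = (ms$msbs - ms$mse) / ms$k,
           sigma_c = (ms$msbm - ms$mse) / ms$n,
           sigma_v = ms$mse)
  }
  tibble(
    component = names(v),
    variance = unname(v),
    sd = suppressWarnings(sqrt(unname(v))),
    negative = unname(v) < 0
  )
}

#' F-test for systematic between-measurement bias
#'
#' Tests the null hypothesis of no bias (one-way random model) with
#' `F = MSBM / MSE` on `(k-1, (n-1)(k-1))` degrees of freedom. Under bias
#' the expected F is roughly `1 + n (sigma_c / sigma_v)^2`, so power grows
#' quickly with the number of subjects.
#'
#' @inheritParams icc1
#' @param alpha Significance level for the `reject` flag.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p.value`, `reject`.
#' @examples
#' bias_f_test(icc_anova(emg_mf()))
#' @export
bias_f_test <- function(anova, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ms <- as_ms_list(anova)
  if (ms$mse <= 0) stop_degenerate("bias F-test undefined: MSE is zero")
  f <- ms$msbm / ms$mse
  df1 <- ms$k - 1
  df2 <- (ms$n - 1) * (ms$k - 1)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  tibble(statistic = f, df1 = df1, df2 = df2, p.value = p,
         reject = p < alpha)
}

#' Population intraclass correlation for a generative model
#'
#' The model-level ICC defined from the generative variances, which the
#' sample formulas estimate: one-way random
#' `sigma_r^2 / (sigma_r^2 + sigma_v^2)`; two-way random, absolute agreement
#' `sigma_r^2 / (sigma_r^2 + sigma_c^2 + sigma_v^2)`; two-way mixed,
#' absolute agreement the same with `theta_c^2 = sum((c_j - cbar)^2)/(k-1)`
#' in place of `sigma_c^2`. The consistency variant omits the bias variance
#' under every model.
#'
#' @param params An `icc_model` parameter set (see [icc_model()]).
#' @param type `"absolute"` or `"consistency"`.
#' @return A length-one double in `[0, 1]`.
#' @examples
#' population_icc(icc_model(1, sigma_r = 10, sigma_v = 5))
#' population_icc(icc_model(3, sigma_r = 10, sigma_v = 5,
#'                          biases = c(1, 6, -1), k = 3))
#' @export
population_icc <- function(params, type = c("absolute", "consistency")) {
  type <- match.arg(type)
  stopifnot(inherits(params, "icc_model"))
  vr <- params$sigma_r^2
  vv <- params$sigma_v^2
  vc <- switch(as.character(params$model),
    "1" = 0,
    "2" = params$sigma_c^2,
    "3" = theta_c2(params$biases)
  )
  if (type == "consistency") vc <- 0
  tot <- vr + vc + vv
  if (tot <= 0) stop_degenerate("population ICC undefined: all variances zero")
  vr / tot
}

# spread of fixed biases about their mean, divisor k - 1
theta_c2 <- function(biases) {
  sum((biases - mean(biases))^2) / (length(biases) - 1)
}

#' Large-sample expectation of ICC(1) when bias is present
#'
#' Applying the one-way estimator ICC(1) to data generated under the two-way
#' random model yields, in expectation,
#' `(sigma_r^2 - sigma_c^2/k) / (sigma_r^2 + sigma_c^2 + sigma_v^2 - sigma_c^2/k)`,
#' which equals neither the absolute-agreement nor the one-way population
#' ICC once `sigma_c > 0`. Provided as a test oracle documenting why ICC(1)
#' must not be reported in the presence of bias.
#'
#' @param params An `icc_model` parameter set with `model = 2`.
#' @return A length-one double.
#' @export
biased_icc1_expectation <- function(params) {
  stopifnot(inherits(params, "icc_model"), params$model == 2)
  vr <- params$sigma_r^2
  vc <- params$sigma_c^2
  vv <- params$sigma_v^2
  k <- params$k
  (vr - vc / k) / (vr + vc + vv - vc / k)
}

#' Qualitative reliability band for an ICC value
#'
#' Conventional interpretation bands: poor below 0.5, moderate 0.5-0.75,
#' good 0.75-0.9, excellent above 0.9. Boundary values fall in the lower
#' band at 0.5 and in `moderate`/`good`/`excellent` at the upper edges
#' (closed on the right).
#'
#' @param icc Numeric vector of ICC values.
#' @return A character vector.
#' @export
icc_band <- function(icc) {
  out <- character(length(icc))
  out[icc < 0.5] <- "poor"
  out[icc >= 0.5 & icc <= 0.75] <- "moderate"
  out[icc > 0.75 & icc <= 0.9] <- "good"
  out[icc > 0.9] <- "excellent"
  out
}
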