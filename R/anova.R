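# Repeated-measures ANOVA decomposition of a complete n x k score matrix.
#
# The five sums of squares partition the total variation around the grand
# mean into between-subject, between-measurement and residual parts:
#   SST  = sum_ij (x_ij - xbar)^2
#   SSBS = k * sum_i (S_i - xbar)^2          (S_i = subject means)
#   SSBM = n * sum_j (M_j - xbar)^2          (M_j = measurement means)
#   SSE  = sum_ij (x_ij - S_i - M_j + xbar)^2
#   SSWS = SST - SSBS,  SSWM = SST - SSBM
# SSE is computed from the residual pattern directly so it is nonnegative
# by construction; the additivity identities then hold to rounding error.

ms_from_matrix <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  gm <- mean(x)
  S <- rowMeans(x)
  M <- colMeans(x)
  sst <- sum((x - gm)^2)
  ssbs <- k * sum((S - gm)^2)
  ssbm <- n * sum((M - gm)^2)
  resid <- x - outer(S, rep(1, k)) - outer(rep(1, n), M) + gm
  sse <- sum(resid^2)
  ssws <- sum(sweep(x, 1, S)^2)
  sswm <- sum(sweep(x, 2, M)^2)
  list(
    n = n, k = k, grand_mean = gm,
    ssbs = ssbs, ssws = ssws, ssbm = ssbm, sswm = sswm, sse = sse, sst = sst,
    msbs = ssbs / (n - 1),
    msws = ssws / (n * (k - 1)),
    msbm = ssbm / (k - 1),
    mswm = sswm / (k * (n - 1)),
    mse  = sse / ((n - 1) * (k - 1)),
    mst  = sst / (n * k - 1)
  )
}

#' Repeated-measures ANOVA table for a score matrix
#'
#' Decomposes the variation of a complete subjects-by-measurements score
#' matrix into sums of squares and mean squares: between subjects (BS),
#' within subjects (WS), between measurements (BM), within measurements
#' (WM), error (E, the residual after removing both main effects) and total.
#' These mean squares are the raw material of every single-score ICC
#' estimator in the package.
#'
#' @param data A data frame, matrix or `score_matrix`; rows are subjects,
#'   columns are measurements (see [as_score_matrix()]).
#' @return A tibble of class `icc_anova` with columns `term`
#'   (`subjects`, `within_subjects`, `measurements`, `within_measurements`,
#'   `error`, `total`), `df`, `sumsq` and `meansq`, carrying `n` and `k` as
#'   attributes.
#' @examples
#' icc_anova(emg_mf())
#' @export
icc_anova <- function(data) {
  x <- as_score_matrix(data)
  ms <- ms_from_matrix(x)
  n <- ms$n
  k <- ms$k
  out <- tibble(
    term = c("subjects", "within_subjects", "measurements",
             "within_measurements", "error", "total"),
    df = c(n - 1, n * (k - 1), k - 1, k * (n - 1), (n - 1) * (k - 1),
           n * k - 1),
    sumsq = c(ms$ssbs, ms$ssws, ms$ssbm, ms$sswm, ms$sse, ms$sst),
    meansq = c(ms$msbs, ms$msws, ms$msbm, ms$mswm, ms$mse, ms$mst)
  )
  structure(out, class = c("icc_anova", class(out)),
            n = n, k = k, grand_mean = ms$grand_mean)
}

# Recover the mean-square list from either an icc_anova tibble or a raw
# matrix/data frame; all estimators funnel through this.
as_ms_list <- function(x) {
  if (inherits(x, "icc_anova")) {
    ms <- setNames(x$meansq, x$term)
    ss <- setNames(x$sumsq, x$term)
    list(
      n = attr(x, "n"), k = attr(x, "k"),
      msbs = ms[["subjects"]], msws = ms[["within_subjects"]],
      msbm = ms[["measurements"]], mswm = ms[["within_measurements"]],
      mse = ms[["error"]], mst = ms[["total"]],
      ssbs = ss[["subjects"]], ssws = ss[["within_subjects"]],
      ssbm = ss[["measurements"]], sswm = ss[["within_measurements"]],
      sse = ss[["error"]], sst = ss[["total"]]
    )
  } else {
    ms_from_matrix(as_score_matrix(x))
  }
}
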