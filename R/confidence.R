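#' Empirical central range of a simulated distribution
#'
#' The interval between the low and high order statistics that cut off a
#' fraction `(1 - level)/2` of the sample in each tail: with
#' `m = floor(((1 - level)/2) * N)`, the lower limit is the m-th smallest
#' value (the highest value among the m lowest) and the upper limit is the
#' m-th largest (the lowest among the m highest). For `N = 10000` and
#' `level = 0.95` this takes the 250th and 9751st order statistics.
#'
#' @param values Non-empty numeric vector.
#' @param level Coverage fraction in (0, 1), default 0.95.
#' @return A one-row tibble: `lower`, `upper`, `level`, `n`.
#' @examples
#' central_range(1:10000)  # lower 250, upper 9751
#' @export
central_range <- function(values, level = 0.95) {
  stopifnot(is.numeric(values), level > 0, level < 1)
  values <- values[!is.na(values)]
  N <- length(values)
  if (N == 0) stop_degenerate("central range of an empty sample")
  m <- floor(((1 - level) / 2) * N)
  if (m < 1) {
    stop_degenerate(sprintf(
      "sample of %d values is too small for a %g%% central range", N,
      100 * level))
  }
  s <- sort(values)
  tibble(lower = s[m], upper = s[N - m + 1], level = level, n = N)
}

#' Analytic F-based confidence intervals for single-score ICCs
#'
#' Standard F-distribution intervals for ICC(1), ICC(A,1) and ICC(C,1)
#' (McGraw and Wong, 1996). For ICC(1) the observed `F = MSBS/MSWS` is
#' divided/multiplied by the appropriate F quantile on `(n-1, n(k-1))`
#' degrees of freedom and transformed back to the ICC scale; ICC(C,1) uses
#' MSE with `(n-1, (n-1)(k-1))` df; ICC(A,1) uses a Satterthwaite
#' approximation for the denominator degrees of freedom.
#'
#' @param anova An `icc_anova` table or score data.
#' @param type One or more of `"icc1"`, `"icc_a1"`, `"icc_c1"` (default all
#'   three).
#' @param level Confidence level, default 0.95.
#' @return A tibble with one row per requested type: `type`, `estimate`,
#'   `conf.low`, `conf.high`, `level`, and `degenerate` flagging an
#'   estimate of exactly 1 (zero error mean square), where the interval
#'   collapses to `(estimate, 1)`.
#' @examples
#' icc_confint(icc_anova(emg_mf()))
#' @export
icc_confint <- function(anova, type = c("icc1", "icc_a1", "icc_c1"),
                        level = 0.95) {
  type <- match.arg(type, several.ok = TRUE)
  stopifnot(level > 0, level < 1)
  ms <- as_ms_list(anova)
  n <- ms$n
  k <- ms$k
  q <- 1 - (1 - level) / 2
  rows <- lapply(type, function(tt) {
    est <- switch(tt,
      icc1 = icc1_value(ms),
      icc_a1 = icc_a1_value(ms),
      icc_c1 = icc_c1_value(ms))
    if (est >= 1) {
      return(tibble(type = tt, estimate = est, conf.low = est,
                    conf.high = 1, level = level, degenerate = TRUE))
    }
    ci <- switch(tt,
      icc1 = {
        df2 <- n * (k - 1)
        fo <- ms$msbs / ms$msws
        fl <- fo / qf(q, n - 1, df2)
        fu <- fo * qf(q, df2, n - 1)
        c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
      },
      icc_c1 = {
        df2 <- (n - 1) * (k - 1)
        fo <- ms$msbs / ms$mse
        fl <- fo / qf(q, n - 1, df2)
        fu <- fo * qf(q, df2, n - 1)
        c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
      },
      icc_a1 = {
        a <- k * est / (n * (1 - est))
        b <- 1 + k * est * (n - 1) / (n * (1 - est))
        v <- (a * ms$msbm + b * ms$mse)^2 /
          ((a * ms$msbm)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
        f1 <- qf(q, n - 1, v)
        f2 <- qf(q, v, n - 1)
        lo <- n * (ms$msbs - f1 * ms$mse) /
          (f1 * (k * ms$msbm + (k * n - k - n) * ms$mse) + n * ms$msbs)
        up <- n * (f2 * ms$msbs - ms$mse) /
          (k * ms$msbm + (k * n - k - n) * ms$mse + n * f2 * ms$msbs)
        c(lo, up)
      })
    tibble(type = tt, estimate = est, conf.low = ci[1], conf.high = ci[2],
           level = level, degenerate = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Central-range curves of ICC(1) over a population-ICC grid
#'
#' For each population ICC value rho on a grid, simulates `N` one-way
#' random-model matrices with variances chosen so that
#' `sigma_r^2/(sigma_r^2 + sigma_v^2) = rho` (the sampling distribution of
#' every ICC estimator depends on the variances only through this ratio),
#' computes ICC(1) per matrix, and records the empirical central range.
#' Read vertically the curves give the central range of the sample ICC for
#' a known rho; read horizontally they give simulation-based confidence
#' limits for rho given an observed sample ICC (see
#' [icc_confint_simulated()]). The same curves apply to ICC(C,1), whose
#' distribution is unaffected by bias.
#'
#' @param n,k Design size of each simulated matrix.
#' @param rho Grid of population ICC values in `[0, 1)`; default 0 to 0.99
#'   in steps of 0.01.
#' @param N Replicates per grid point (default 10000).
#' @param level Central-range coverage (default 0.95).
#' @param seed Optional integer seed for the whole curve.
#' @return A tibble of class `icc_conf_curve` with columns `rho`, `lower`,
#'   `upper`; attributes `n`, `k`, `level`, `N`.
#' @export
icc_conf_curve <- function(n, k, rho = seq(0, 0.99, by = 0.01), N = 10000,
                           level = 0.95, seed = NULL) {
  stopifnot(all(rho >= 0), all(rho < 1), !is.unsorted(rho))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(rho, function(p) {
    params <- icc_model(1, mu = 0, sigma_r = sqrt(p), sigma_v = sqrt(1 - p),
                        n = n, k = k)
    ms <- simulate_ms_batch(params, N)
    den <- ms$msbs + (k - 1) * ms$msws
    vals <- (ms$msbs - ms$msws) / den
    cr <- central_range(vals[den > 0], level = level)
    tibble(rho = p, lower = cr$lower, upper = cr$upper)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("icc_conf_curve", class(out)),
            n = n, k = k, level = level, N = N)
}

# invert a monotone (up to Monte Carlo noise) curve: smallest / largest rho
# at which curve(rho) crosses `target`, linear interpolation between grid
# points, as in a graphical reading of the central-range diagram.
invert_curve <- function(rho, curve, target, side) {
  if (side == "lower") {
    # smallest rho with curve (upper central-range limit) >= target
    idx <- which(curve >= target)
    if (length(idx) == 0) {
      stop_degenerate("sample ICC above the simulated curve for every rho on the grid")
    }
    i <- min(idx)
    if (i == 1) return(rho[1])
    approx(x = curve[(i - 1):i], y = rho[(i - 1):i], xout = target,
           ties = "ordered")$y
  } else {
    # largest rho with curve (lower central-range limit) <= target
    idx <- which(curve <= target)
    if (length(idx) == 0) {
      stop_degenerate("sample ICC below the simulated curve for every rho on the grid")
    }
    i <- max(idx)
    if (i == length(rho)) return(rho[length(rho)])
    approx(x = curve[i:(i + 1)], y = rho[i:(i + 1)], xout = target,
           ties = "ordered")$y
  }
}

#' Simulation-based confidence limits for the population ICC
#'
#' Inverts the central-range curves of [icc_conf_curve()]: the lower
#' confidence limit is the smallest population ICC whose upper central-range
#' limit reaches the observed sample ICC, and the upper confidence limit is
#' the largest population ICC whose lower central-range limit does not
#' exceed it. Values between grid points are obtained by linear
#' interpolation. Applicable to a sample ICC(1) or — because its
#' distribution is bias-invariant — a sample ICC(C,1).
#'
#' @param icc Observed sample ICC, in `[0, 1)` (negative estimates clip the
#'   lower limit at 0 automatically).
#' @param n,k Design size of the study the ICC came from.
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed passed to [icc_conf_curve()].
#' @param curve Optional precomputed `icc_conf_curve` to reuse across
#'   queries; must match `n`, `k` and `level`.
#' @param ... Further arguments (`rho`, `N`) forwarded to
#'   [icc_conf_curve()].
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`, `level`,
#'   `method`.
#' @export
icc_confint_simulated <- function(icc, n, k, level = 0.95, seed = NULL,
                                  curve = NULL, ...) {
  stopifnot(icc < 1)
  if (is.null(curve)) {
    curve <- icc_conf_curve(n, k, level = level, seed = seed, ...)
  } else {
    stopifnot(inherits(curve, "icc_conf_curve"))
    if (attr(curve, "n") != n || attr(curve, "k") != k ||
        attr(curve, "level") != level) {
      abort("supplied curve was built for a different n, k or level")
    }
  }
  lo <- if (icc <= curve$upper[1]) curve$rho[1] else {
    invert_curve(curve$rho, curve$upper, icc, "lower")
  }
  hi <- invert_curve(curve$rho, curve$lower, icc, "upper")
  tibble(estimate = icc, conf.low = lo, conf.high = hi, level = level,
         method = "simulated")
}
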