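#' Generative model parameters for a reliability study
#'
#' Defines the data-generating process `x_ij = mu + r_i + c_j + v_ij` for an
#' n x k score matrix:
#' model 1 (one-way random): no bias term, `c_j = 0`;
#' model 2 (two-way random): `c_j ~ N(0, sigma_c^2)`, redrawn per matrix;
#' model 3 (two-way mixed): `c_j` fixed constants, identical in every
#' replicate. In all models `r_i ~ N(0, sigma_r^2)` (one draw per subject)
#' and `v_ij ~ N(0, sigma_v^2)` (one draw per cell); the noise term absorbs
#' both the subject-by-measurement interaction and the residual error, whose
#' variances enter only through their sum.
#'
#' @param model 1, 2 or 3.
#' @param mu Population mean of the true scores (default 100).
#' @param sigma_r SD of the subject effects (default 10).
#' @param sigma_v SD of the noise.
#' @param sigma_c SD of the random biases (model 2; default 0).
#' @param biases Numeric vector of exactly `k` fixed biases (model 3).
#' @param n,k Numbers of subjects and of repeated measurements.
#' @return A list of class `icc_model`.
#' @examples
#' icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 5, n = 20, k = 3)
#' @export
icc_model <- function(model, mu = 100, sigma_r = 10, sigma_v = 5,
                      sigma_c = 0, biases = NULL, n = 20, k = 3) {
  model <- as.integer(model)
  stopifnot(model %in% 1:3, sigma_r >= 0, sigma_v >= 0, sigma_c >= 0,
            n >= 2, k >= 2)
  if (model == 3) {
    if (is.null(biases) || length(biases) != k || !is.numeric(biases)) {
      abort("model 3 requires exactly k fixed biases")
    }
  } else if (!is.null(biases)) {
    abort("fixed biases are only meaningful for model 3")
  }
  if (model != 2 && sigma_c != 0) {
    abort("sigma_c applies to model 2 only")
  }
  structure(
    list(model = model, mu = mu, sigma_r = sigma_r, sigma_v = sigma_v,
         sigma_c = sigma_c, biases = biases, n = as.integer(n),
         k = as.integer(k)),
    class = "icc_model"
  )
}

#' @export
print.icc_model <- function(x, ...) {
  lbl <- c("one-way random", "two-way random", "two-way mixed")[x$model]
  cat(sprintf("<icc_model %d (%s): n=%d k=%d mu=%g sigma_r=%g sigma_v=%g",
              x$model, lbl, x$n, x$k, x$mu, x$sigma_r, x$sigma_v))
  if (x$model == 2) cat(sprintf(" sigma_c=%g", x$sigma_c))
  if (x$model == 3) cat(" biases=(", paste(x$biases, collapse = ", "), ")")
  cat(">\n")
  invisible(x)
}

#' Simulate one score matrix from a generative model
#'
#' Draws a single n x k matrix according to the sampling rules of
#' [icc_model()]. Uses the current RNG state; call `set.seed()` for
#' reproducibility.
#'
#' @param params An `icc_model`.
#' @return A `score_matrix`.
#' @examples
#' set.seed(1)
#' simulate_scores(icc_model(1, sigma_r = 10, sigma_v = 5, n = 5, k = 3))
#' @export
simulate_scores <- function(params) {
  stopifnot(inherits(params, "icc_model"))
  n <- params$n
  k <- params$k
  r <- rnorm(n, 0, params$sigma_r)
  cj <- switch(as.character(params$model),
    "1" = rep(0, k),
    "2" = rnorm(k, 0, params$sigma_c),
    "3" = params$biases
  )
  v <- matrix(rnorm(n * k, 0, params$sigma_v), n, k)
  x <- params$mu + outer(r, rep(1, k)) + outer(rep(1, n), cj) + v
  as_score_matrix(x)
}

# Vectorized batch: simulate `N` replicate matrices and return the per-
# replicate mean squares as an N x 6 data.frame, without materialising each
# matrix separately. Cells are laid out column-major (subject fastest) in a
# (n*k) x N matrix; subject and measurement sums come from rowsum() over the
# corresponding index.
simulate_ms_batch <- function(params, N) {
  n <- params$n
  k <- params$k
  subj <- rep(seq_len(n), times = k)
  meas <- rep(seq_len(k), each = n)

  # draw order (r, then c, then v) matches simulate_scores() so that a
  # batch of size 1 reproduces the scalar path draw-for-draw
  r <- matrix(rnorm(n * N, 0, params$sigma_r), n, N)
  x <- r[subj, , drop = FALSE]
  if (params$model == 2) {
    cj <- matrix(rnorm(k * N, 0, params$sigma_c), k, N)
    x <- x + cj[meas, , drop = FALSE]
  } else if (params$model == 3) {
    x <- x + params$biases[meas]
  }
  x <- x + matrix(rnorm(n * k * N, 0, params$sigma_v), n * k, N)
  # mu shifts every cell equally and cancels from all SS; added for fidelity
  x <- x + params$mu

  gm <- colMeans(x)
  S <- rowsum(x, subj) / k          # n x N subject means
  M <- rowsum(x, meas) / n          # k x N measurement means
  sst <- colSums(sweep(x, 2, gm)^2)
  ssbs <- k * colSums(sweep(S, 2, gm)^2)
  ssbm <- n * colSums(sweep(M, 2, gm)^2)
  sse <- pmax(sst - ssbs - ssbm, 0)
  ssws <- sst - ssbs
  sswm <- sst - ssbm
  data.frame(
    msbs = ssbs / (n - 1),
    msws = ssws / (n * (k - 1)),
    msbm = ssbm / (k - 1),
    mswm = sswm / (k * (n - 1)),
    mse = sse / ((n - 1) * (k - 1)),
    mst = sst / (n * k - 1)
  )
}

#' Monte Carlo simulation of the ICC sampling distributions
#'
#' Simulates `N` independent score matrices from a generative model, runs
#' the repeated-measures ANOVA on each, and records the three single-score
#' ICC estimators and the bias F statistic per replicate, together with
#' summary statistics: means and SDs of each ICC and mean square, the
#' empirical central range of each ICC, the mean per-matrix ratio
#' ICC(C,1)/ICC(A,1), and the fraction of matrices with ICC(C,1) >
#' ICC(A,1).
#'
#' @param params An `icc_model`.
#' @param N Number of replicate matrices (default 10000, minimum 100).
#' @param seed Optional integer seed; identical seed and parameters give an
#'   identical result.
#' @param level Level of the reported central ranges (default 0.95).
#' @param chunk_size Internal batch size in matrices. Random numbers are
#'   drawn chunk by chunk, so the chunk size is part of the reproducibility
#'   conditions along with the seed; the default is fixed.
#' @return An object of class `icc_sim`: a list with `draws` (a tibble with
#'   one row per replicate: the six mean squares, `icc1`, `icc_a1`,
#'   `icc_c1`, `f`), `summary`, `central_ranges`, `ratio` (see
#'   [ratio_statistics()]), `params`, `N`, `seed`, `n_degenerate`.
#' @examples
#' sim <- icc_simulate(icc_model(1, sigma_r = 10, sigma_v = 5, n = 20, k = 3),
#'                     N = 500, seed = 42)
#' sim$summary
#' @export
icc_simulate <- function(params, N = 10000, seed = NULL, level = 0.95,
                         chunk_size = 50000) {
  stopifnot(inherits(params, "icc_model"), N >= 100)
  if (!is.null(seed)) set.seed(seed)
  if (params$sigma_r == 0 && params$sigma_v == 0 &&
      (params$model != 2 || params$sigma_c == 0)) {
    stop_degenerate("all variances zero: every replicate is a constant matrix")
  }

  n <- params$n
  k <- params$k
  chunk_n <- max(1L, min(as.integer(chunk_size),
                         as.integer(5e6 / (n * k))))
  pieces <- vector("list", ceiling(N / chunk_n))
  done <- 0L
  i <- 1L
  while (done < N) {
    m <- min(chunk_n, N - done)
    pieces[[i]] <- simulate_ms_batch(params, m)
    done <- done + m
    i <- i + 1L
  }
  ms <- dplyr::bind_rows(pieces)

  den1 <- ms$msbs + (k - 1) * ms$msws
  denA <- ms$msbs + (k - 1) * ms$mse + (k / n) * (ms$msbm - ms$mse)
  denC <- ms$msbs + (k - 1) * ms$mse
  bad <- den1 <= 0 | denA <= 0 | denC <= 0 | ms$mse <= 0
  n_degenerate <- sum(bad)
  if (n_degenerate > 0) {
    warn(sprintf("%d degenerate replicate(s) produced NA ICCs", n_degenerate))
  }
  draws <- as_tibble(ms)
  draws$icc1 <- ifelse(den1 > 0, (ms$msbs - ms$msws) / den1, NA_real_)
  draws$icc_a1 <- ifelse(denA > 0, (ms$msbs - ms$mse) / denA, NA_real_)
  draws$icc_c1 <- ifelse(denC > 0, (ms$msbs - ms$mse) / denC, NA_real_)
  draws$f <- ifelse(ms$mse > 0, ms$msbm / ms$mse, NA_real_)

  stat_cols <- c("icc1", "icc_a1", "icc_c1", "f",
                 "msbs", "msws", "msbm", "mswm", "mse", "mst")
  summary <- tibble(
    statistic = stat_cols,
    mean = unname(vapply(draws[stat_cols], mean, numeric(1), na.rm = TRUE)),
    sd = unname(vapply(draws[stat_cols], sd, numeric(1), na.rm = TRUE))
  )
  central_ranges <- dplyr::bind_rows(lapply(
    c("icc1", "icc_a1", "icc_c1"),
    function(col) {
      cr <- central_range(draws[[col]][!is.na(draws[[col]])], level = level)
      tibble(statistic = col, lower = cr$lower, upper = cr$upper,
             level = level)
    }
  ))

  out <- list(draws = draws, summary = summary,
              central_ranges = central_ranges,
              params = params, N = N, seed = seed,
              level = level, n_degenerate = n_degenerate)
  out$ratio <- ratio_statistics(out)
  structure(out, class = "icc_sim")
}

#' Bias-sensitivity ratio statistics from a simulation
#'
#' For each simulated matrix the ratio ICC(C,1)/ICC(A,1) measures how much
#' the consistency coefficient exceeds the absolute-agreement one; its mean
#' over replicates, and the probability that ICC(C,1) is the larger of the
#' two, are diagnostic of bias: both sit at about 1 and 37-38% without bias
#' and grow steeply with the relative bias `sigma_c / sigma_r`.
#'
#' @param sim An `icc_sim` object.
#' @return A one-row tibble: `mean_ratio`, `prob_c_gt_a`, `n_used`,
#'   `n_excluded` (replicates with ICC(A,1) equal to zero or undefined).
#' @export
ratio_statistics <- function(sim) {
  stopifnot(inherits(sim, "icc_sim") || is.list(sim))
  a <- sim$draws$icc_a1
  cc <- sim$draws$icc_c1
  ok <- !is.na(a) & !is.na(cc) & a != 0
  tibble(
    mean_ratio = mean(cc[ok] / a[ok]),
    prob_c_gt_a = mean(cc[ok] > a[ok]),
    n_used = sum(ok),
    n_excluded = sum(!ok)
  )
}

#' Relative-frequency histogram of simulated values
#'
#' Bins values into equal-width channels and reports the relative frequency
#' `N_i / N` per channel; frequencies sum to 1 over values inside `range`.
#' Bin centers are reported, matching the convention of plotting the ICC at
#' the center of its channel.
#'
#' @param values Numeric vector.
#' @param bins Number of channels (default 100).
#' @param range Two-element numeric range covered by the channels; defaults
#'   to `c(-0.5, 1)`, wide enough for ICC(1) which can go negative.
#' @return A tibble with columns `bin_lower`, `bin_center`, `bin_upper`,
#'   `count`, `rel_freq`.
#' @export
icc_histogram <- function(values, bins = 100, range = c(-0.5, 1)) {
  stopifnot(bins >= 1, length(range) == 2, range[1] < range[2])
  values <- values[!is.na(values)]
  if (length(values) == 0) stop_degenerate("no values to histogram")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= bins
  counts <- tabulate(idx[inside], nbins = bins)
  tibble(
    bin_lower = edges[-(bins + 1)],
    bin_center = (edges[-1] + edges[-(bins + 1)]) / 2,
    bin_upper = edges[-1],
    count = counts,
    rel_freq = counts / sum(counts)
  )
}

#' Expected mean squares under a generative model
#'
#' The population expectations that the simulated average mean squares
#' converge to: `MSBS -> k sigma_r^2 + sigma_v^2`,
#' `MSBM -> n b + sigma_v^2`, `MSWS -> b + sigma_v^2`,
#' `MSWM -> sigma_r^2 + sigma_v^2`, `MSE -> sigma_v^2`, where `b` is
#' `sigma_c^2` (model 2), `theta_c^2` (model 3) or 0 (model 1).
#'
#' @param params An `icc_model`.
#' @return A tibble with columns `statistic` and `expected`.
#' @export
expected_mean_squares <- function(params) {
  stopifnot(inherits(params, "icc_model"))
  vr <- params$sigma_r^2
  vv <- params$sigma_v^2
  b <- switch(as.character(params$model),
    "1" = 0, "2" = params$sigma_c^2, "3" = theta_c2(params$biases))
  tibble(
    statistic = c("msbs", "msbm", "msws", "mswm", "mse"),
    expected = c(params$k * vr + vv, params$n * b + vv, b + vv, vr + vv, vv)
  )
}

#' @export
print.icc_sim <- function(x, digits = 3, ...) {
  lbl <- c("one-way random", "two-way random", "two-way mixed")[x$params$model]
  cat(sprintf("Monte Carlo ICC simulation: model %d (%s), n=%d, k=%d, N=%d\n",
              x$params$model, lbl, x$params$n, x$params$k, x$N))
  s <- x$summary[x$summary$statistic %in% c("icc1", "icc_a1", "icc_c1"), ]
  cr <- x$central_ranges
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s mean %s (%d%% central range %s to %s)\n",
                s$statistic[i], format(round(s$mean[i], digits), nsmall = digits),
                round(100 * x$level),
                format(round(cr$lower[i], digits), nsmall = digits),
                format(round(cr$upper[i], digits), nsmall = digits)))
  }
  cat(sprintf("  mean ICC(C,1)/ICC(A,1) ratio %s, P[C > A] = %.1f%%\n",
              format(round(x$ratio$mean_ratio, digits), nsmall = digits),
              100 * x$ratio$prob_c_gt_a))
  invisible(x)
}
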