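test_that("zero-variance parameters give a constant matrix of mu", {
  p <- icc_model(1, mu = 7, sigma_r = 0, sigma_v = 0, n = 4, k = 3)
  x <- simulate_scores(p)
  expect_true(all(x == 7))
  expect_error(icc_simulate(p, N = 100), class = "iccsim_degenerate")
})

test_that("simulated score moments follow the generative model", {
  set.seed(501)
  # variance of subject means is sigma_r^2 + sigma_v^2/k
  p1 <- icc_model(1, sigma_r = 10, sigma_v = 5, n = 2000, k = 3)
  x <- simulate_scores(p1)
  expect_equal(var(rowMeans(x)), 100 + 25 / 3, tolerance = 0.10)
  expect_equal(mean(x), 100, tolerance = 0.01)
  # fixed biases shift column means by their differences
  p3 <- icc_model(3, sigma_r = 10, sigma_v = 5, biases = c(10, 6, -10),
                  n = 5000, k = 3)
  cm <- colMeans(simulate_scores(p3))
  expect_equal(cm[1] - cm[3], 20, tolerance = 0.5)
  expect_equal(cm[2] - cm[3], 16, tolerance = 0.5)
})

test_that("the vectorized batch engine reproduces the scalar path draw-for-draw", {
  for (p in list(
    icc_model(1, sigma_r = 10, sigma_v = 5, n = 8, k = 3),
    icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 5, n = 8, k = 3),
    icc_model(3, sigma_r = 10, sigma_v = 5, biases = c(1, 6, -1), n = 8, k = 3)
  )) {
    set.seed(77)
    batch <- iccsim:::simulate_ms_batch(p, 1)
    set.seed(77)
    an <- icc_anova(simulate_scores(p))
    expect_equal(batch$msbs, anova_lookup(an, "subjects"), tolerance = 1e-9)
    expect_equal(batch$msbm, anova_lookup(an, "measurements"),
                 tolerance = 1e-9)
    expect_equal(batch$mse, anova_lookup(an, "error"), tolerance = 1e-9)
    expect_equal(batch$msws, anova_lookup(an, "within_subjects"),
                 tolerance = 1e-9)
    expect_equal(batch$mswm, anova_lookup(an, "within_measurements"),
                 tolerance = 1e-9)
  }
})

test_that("identical seed and parameters give identical simulation results", {
  p <- icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 5, n = 10, k = 3)
  s1 <- icc_simulate(p, N = 300, seed = 99)
  s2 <- icc_simulate(p, N = 300, seed = 99)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$summary, s2$summary)
  # a different chunking draws the same normals in a different order, so
  # the summary statistics stay distributionally equivalent
  s3 <- icc_simulate(p, N = 300, seed = 99, chunk_size = 17)
  expect_equal(mean(s3$draws$icc_a1), mean(s1$draws$icc_a1),
               tolerance = 0.1)
})

test_that("average mean squares agree with their expectations for all three models", {
  models <- list(
    icc_model(1, sigma_r = 10, sigma_v = 5, n = 20, k = 3),
    icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 5, n = 20, k = 3),
    icc_model(3, sigma_r = 10, sigma_v = 5, biases = c(1, 6, -1),
              n = 20, k = 3)
  )
  for (i in seq_along(models)) {
    sim <- icc_simulate(models[[i]], N = 10000, seed = 600 + i)
    ems <- expected_mean_squares(models[[i]])
    obs <- sim$summary[match(ems$statistic, sim$summary$statistic), ]
    expect_equal(obs$mean, ems$expected, tolerance = 0.02)
  }
})

test_that("vanishing noise drives every ICC to one", {
  p <- icc_model(1, sigma_r = 10, sigma_v = 1e-4, n = 10, k = 3)
  sim <- icc_simulate(p, N = 200, seed = 5)
  expect_true(all(sim$draws$icc1 > 0.9999))
  expect_true(all(sim$draws$icc_a1 > 0.9999))
  expect_true(all(sim$draws$icc_c1 > 0.9999))
})

test_that("without bias the three ICC distributions coincide per matrix", {
  sim <- icc_simulate(icc_model(1, sigma_r = 10, sigma_v = 5, n = 20, k = 3),
                      N = 2000, seed = 8)
  # per matrix the three estimators are nearly equal under the one-way model
  expect_lt(max(abs(sim$draws$icc_a1 - sim$draws$icc_c1)), 0.15)
  expect_lt(mean(abs(sim$draws$icc1 - sim$draws$icc_c1)), 0.02)
  m <- sim$summary$mean[match(c("icc1", "icc_a1", "icc_c1"),
                              sim$summary$statistic)]
  expect_lt(diff(range(m)), 0.01)
})

test_that("consistency ICC distribution is insensitive to the bias strength", {
  # exact invariance: with identical seeds the per-column biases cancel from
  # MSBS and MSE, so the ICC(C,1) draws are bit-identical across sigma_c
  s5 <- icc_simulate(icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 5,
                               n = 20, k = 3), N = 2000, seed = 1234)
  s10 <- icc_simulate(icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 10,
                                n = 20, k = 3), N = 2000, seed = 1234)
  expect_equal(s5$draws$icc_c1, s10$draws$icc_c1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s5$draws$icc_a1, s10$draws$icc_a1)))
  # distributional invariance across independent streams: the two-sample
  # KS statistic stays at pure-noise level (~0.019 at N = 10000)
  a <- icc_simulate(icc_model(1, sigma_r = 10, sigma_v = 5, n = 20, k = 3),
                    N = 10000, seed = 1234)$draws$icc_c1
  b <- icc_simulate(icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 10,
                              n = 20, k = 3),
                    N = 10000, seed = 1239)$draws$icc_c1
  d <- suppressWarnings(stats::ks.test(a, b))$statistic
  expect_lt(unname(d), 0.04)
  # while the agreement ICC shifts down with bias
  simA0 <- icc_simulate(icc_model(1, sigma_r = 10, sigma_v = 5, n = 20, k = 3),
                        N = 4000, seed = 2)$draws$icc_a1
  simA10 <- icc_simulate(icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 10,
                                   n = 20, k = 3),
                         N = 4000, seed = 3)$draws$icc_a1
  expect_lt(mean(simA10), mean(simA0) - 0.2)
})

test_that("fixed biases give a narrower agreement distribution than random ones", {
  # model 3 at theta_c^2 = sigma_c^2 removes the between-replicate bias draw
  sc <- 5
  biases <- c(-sc, 0, sc)   # theta_c^2 = 25 = sigma_c^2
  sim2 <- icc_simulate(icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = sc,
                                 n = 20, k = 3), N = 4000, seed = 31)
  sim3 <- icc_simulate(icc_model(3, sigma_r = 10, sigma_v = 5,
                                 biases = biases, n = 20, k = 3),
                       N = 4000, seed = 32)
  expect_lt(sd(sim3$draws$icc_a1), sd(sim2$draws$icc_a1))
})

test_that("two-way variance components are recovered from large-n simulations", {
  # sigma_c^2 is estimated from k - 1 = 2 bias draws per matrix, so its
  # per-replicate SD is about sigma_c^2; N = 5000 puts the MC standard
  # error well inside the 5% recovery band
  p <- icc_model(2, sigma_r = 10, sigma_v = 5, sigma_c = 5, n = 2000, k = 3)
  sim <- icc_simulate(p, N = 5000, seed = 41)
  vr <- mean((sim$draws$msbs - sim$draws$mse) / p$k)
  vc <- mean((sim$draws$msbm - sim$draws$mse) / p$n)
  vv <- mean(sim$draws$mse)
  expect_equal(vr, 100, tolerance = 0.05)
  expect_equal(vc, 25, tolerance = 0.05)
  expect_equal(vv, 25, tolerance = 0.05)
})

test_that("ICC(1) of the average mean squares matches its biased expectation", {
  # the biased expectation is the ICC(1) formula evaluated at the expected
  # mean squares; the mean of per-matrix ICC(1) values sits above it
  # (mean-of-ratio vs ratio-of-means), as the survey tables also show
  p <- icc_model(2, sigma_r = 10, sigma_c = 10, sigma_v = 5, n = 500, k = 3)
  sim <- icc_simulate(p, N = 2000, seed = 51)
  msbs <- mean(sim$draws$msbs)
  msws <- mean(sim$draws$msws)
  icc1_of_means <- (msbs - msws) / (msbs + (p$k - 1) * msws)
  expect_equal(icc1_of_means, biased_icc1_expectation(p), tolerance = 0.02)
  expect_gt(mean(sim$draws$icc1), biased_icc1_expectation(p))
})

test_that("mean of per-matrix ICCs differs from the ICC of mean squares by little", {
  sim <- icc_simulate(icc_model(1, sigma_r = 10, sigma_v = 5, n = 20, k = 3),
                      N = 5000, seed = 61)
  mean_of_ratio <- mean(sim$draws$icc1)
  msbs <- mean(sim$draws$msbs)
  msws <- mean(sim$draws$msws)
  ratio_of_means <- (msbs - msws) / (msbs + 2 * msws)
  cr <- sim$central_ranges
  width <- cr$upper[cr$statistic == "icc1"] - cr$lower[cr$statistic == "icc1"]
  expect_false(isTRUE(all.equal(mean_of_ratio, ratio_of_means,
                                tolerance = 1e-6)))
  expect_lt(abs(mean_of_ratio - ratio_of_means), 0.2 * width)
})

test_that("ratio statistics track the bias strength", {
  # no bias: ratio near 1, probability of C > A near 37%
  sim0 <- icc_simulate(icc_model(1, sigma_r = 10, sigma_v = 5, n = 20, k = 3),
                       N = 5000, seed = 71)
  expect_equal(sim0$ratio$mean_ratio, 1.000, tolerance = 0.005)
  expect_equal(sim0$ratio$prob_c_gt_a, 0.37, tolerance = 0.1)
  # moderate bias and noise: ratio about 1.2, probability about 96%
  simb <- icc_simulate(icc_model(2, sigma_r = 10, sigma_c = 5, sigma_v = 5,
                                 n = 20, k = 3), N = 5000, seed = 72)
  expect_equal(simb$ratio$mean_ratio, 1.215, tolerance = 0.05)
  expect_gt(simb$ratio$prob_c_gt_a, 0.9)
})

test_that("histograms report relative frequencies that sum to one", {
  set.seed(81)
  h1 <- icc_histogram(rep(0.5, 10000), bins = 10, range = c(0, 1))
  expect_equal(sum(h1$rel_freq), 1, tolerance = 1e-9)
  # channels are closed on the left, so 0.5 lands in [0.5, 0.6)
  expect_equal(h1$rel_freq[6], 1)
  hu <- icc_histogram(runif(20000), bins = 10, range = c(0, 1))
  expect_equal(hu$rel_freq, rep(0.1, 10), tolerance = 0.15)
  sim <- icc_simulate(icc_model(1, sigma_r = 10, sigma_v = 5, n = 20, k = 3),
                      N = 5000, seed = 82)
  h <- icc_histogram(sim$draws$icc1)
  expect_equal(sum(h$rel_freq), 1, tolerance = 1e-9)
  # mode near the population ICC of 0.8
  expect_equal(h$bin_center[which.max(h$rel_freq)], 0.8, tolerance = 0.1)
  expect_error(icc_histogram(numeric(0)), class = "iccsim_degenerate")
})
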