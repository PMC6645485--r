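Package: iccsim
Title: Single-Score Intraclass Correlation Estimation and Monte Carlo
    Simulation for Reliability Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes single-score intraclass correlation coefficients
    (ICC(1), ICC(A,1), ICC(C,1)) from a complete subjects-by-measurements
    score matrix via repeated-measures ANOVA, together with variance
    components under the one-way random, two-way random, and two-way mixed
    models, an F-test for systematic between-measurement bias, analytic
    F-based confidence intervals, and a Monte Carlo simulator of the three
    generative models. The simulator reproduces the full sampling
    distribution of each ICC estimator, its empirical central range, and a
    simulation-based inversion of the central-range curves that yields
    confidence limits for the population ICC. Includes a model-agnostic
    analysis recipe that reports absolute-agreement and consistency ICCs
    and decides whether measurement bias is negligible.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
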