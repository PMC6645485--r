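---
title: "Single-score ICC estimation and simulation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-score ICC estimation and simulation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iccsim)
```

## The data and the decomposition

A reliability study yields a complete $n \times k$ matrix $x_{ij}$: $n$
subjects in rows, $k$ repeated measurements (raters, occasions, days) in
columns. Orientation is fixed — the package never transposes — and
incomplete matrices are rejected rather than imputed; unbalanced designs
are out of scope.

`icc_anova()` partitions the total sum of squares around the grand mean
$\bar x$ into the between-subject, between-measurement and residual parts,

$$SST = SSBS + SSBM + SSE, \qquad SSWS = SSBM + SSE, \qquad SSWM = SSBS + SSE,$$

with mean squares $MS = SS/df$ on $df_{BS}=n-1$, $df_{BM}=k-1$,
$df_{WS}=n(k-1)$, $df_{WM}=k(n-1)$ and $df_E=(n-1)(k-1)$ degrees of
freedom. $SSE$ is accumulated directly from the double-centred residuals
$x_{ij} - S_i - M_j + \bar x$, which keeps it nonnegative by construction;
the additivity identities then hold to about $10^{-12}$ relative error and
are tested at $10^{-9}$. A constant matrix gives all $SS = 0$; downstream
estimators treat the resulting zero denominators as a degenerate-input
condition (a classed error) rather than returning `NaN`.

## Generative models

All inference refers to three nested generative models for a cell score:

* **Model 1, one-way random**: $x_{ij} = \mu + r_i + v_{ij}$;
* **Model 2, two-way random**: adds a per-measurement bias
  $c_j \sim N(0, \sigma_c^2)$, redrawn for every replicate matrix;
* **Model 3, two-way mixed**: the $c_j$ are fixed constants, identical in
  every replicate; their spread is
  $\theta_c^2 = \sum_j (c_j - \bar c)^2/(k-1)$.

$r_i \sim N(0, \sigma_r^2)$ is the subject's true-score deviation and
$v_{ij} \sim N(0, \sigma_v^2)$ is noise. The subject-by-measurement
interaction and the residual error are not modelled separately: only their
sum is identifiable from a single matrix, so the noise term absorbs both.
No sum-to-zero restriction is placed on the fixed biases of model 3 —
adding a common constant to every $c_j$ shifts the whole matrix and
cancels from every sum of squares, a translation invariance the test suite
checks explicitly. Models 2 and 3 lead to the same sample formulas, so the
estimators never branch on the model.

The estimators and the population quantities they target:

| | population value | sample estimator |
|---|---|---|
| one-way | $\rho = \sigma_r^2 / (\sigma_r^2 + \sigma_v^2)$ | `icc1()` |
| absolute agreement | $\sigma_r^2 / (\sigma_r^2 + b + \sigma_v^2)$, $b = \sigma_c^2$ or $\theta_c^2$ | `icc_a1()` |
| consistency | $\sigma_r^2 / (\sigma_r^2 + \sigma_v^2)$ | `icc_c1()` |

Negative sample ICCs and negative variance-component estimates are
legitimate small-sample outcomes; both are returned as-is with a flag,
never truncated to zero, since truncation would bias any downstream
averaging.

## The analysis recipe and its parameters

`icc_analyze()` deliberately avoids asking the user to pick a model up
front. It computes all three estimators and decides what is reportable
from the data:

* **`alpha` (default 0.05)** — level of the bias F-test,
  $F = MSBM/MSE$ on $(k-1, (n-1)(k-1))$ df. Under bias the expected F is
  roughly $1 + n(\sigma_c/\sigma_v)^2$: power grows with $n$, so with many
  subjects even a trivially small bias becomes significant — which is why
  the estimated $\sigma_c$ is always reported alongside, in measurement
  units.
* **`ratio_threshold` (default 1.02)** — an advisory cut-off on
  ICC(C,1)/ICC(A,1). Simulation under the no-bias model puts this ratio
  within a fraction of a percent of 1, while a relative bias
  $\sigma_c/\sigma_r \approx 0.5$ already pushes it past 1.1, so "within a
  couple of percent" separates the regimes; the exact value is a
  convention, and the F-test, not the ratio, drives the conclusion.
* **`level` (default 0.95)** and **`ci`** — confidence intervals are
  analytic by default (F-based formulas; ICC(A,1) uses a Satterthwaite
  approximation for the denominator df). `ci = "simulated"` replaces the
  ICC(1) and ICC(C,1) intervals by the central-range inversion described
  below; ICC(A,1) keeps its analytic interval because the inversion curves
  are built under the no-bias model, which does not bound the agreement
  coefficient when bias is present.

ICC(1) is flagged "not reportable" whenever the F-test rejects: under bias
its expectation (available as `biased_icc1_expectation()`) matches neither
population coefficient, so printing it would mislead. Qualitative bands
follow the common convention (poor < 0.5, moderate 0.5–0.75, good
0.75–0.9, excellent > 0.9), with closed right boundaries — a choice the
literature leaves open.

## The simulator

`icc_simulate()` draws $N$ matrices, runs the ANOVA on each, and keeps the
per-replicate mean squares, ICCs and F statistics. Defaults follow the
package's reference settings $\mu = 100$, $\sigma_r = 10$, $N = 10000$;
every ICC sampling distribution depends on the variances only through the
ratios $\sigma_v/\sigma_r$ and $\sigma_c/\sigma_r$, so those two ratios
(plus $n$ and $k$) are the real degrees of freedom of a simulation design.
Replicates are generated in vectorized chunks (`rowsum()` over subject and
measurement indices); a batch of size one reproduces the scalar
`simulate_scores()` path draw-for-draw, which the tests use as a
cross-check. Randomness is R's default Mersenne-Twister stream under a
single integer seed; chunk size participates in the draw order, so
reproducibility is stated for a fixed seed, parameters and (default)
chunking. Per-replicate draws are kept in memory — at the design sizes of
interest this is tens of megabytes, and the chunk limit caps transient
allocations.

Two summaries deserve comment:

* the **central range** at level $1-\alpha$ is the interval between the
  $m$-th smallest and $m$-th largest of the $N$ simulated values, with
  $m = \lfloor (\alpha/2) N \rfloor$ (for $N = 10000$ at 95%, the 250th
  and 9751st order statistics). It needs $m \ge 1$, i.e. at least
  $2/(1-\text{level})$ values.
* the **mean of per-matrix ICCs is not the ICC of the mean squares**.
  The distinction matters: the biased-ICC(1) expectation formula describes
  the estimator applied to the *expected* mean squares, and the tests
  assert it on exactly that quantity. The per-matrix mean sits visibly
  above it whenever $k$ is small, because the bias spread is estimated
  from only $k-1$ effective draws per matrix and the ICC is convex in it.

Histograms (`icc_histogram()`) use 100 equal-width bins over $[-0.5, 1]$
by default — wide enough to show the negative tail that small-$n$ designs
produce — with left-closed bins so each value lands in exactly one channel
and relative frequencies sum to one.

## Simulation-based confidence limits

`icc_conf_curve()` maps each grid value $\rho$ to the one-way model with
$\sigma_r = \sqrt\rho$, $\sigma_v = \sqrt{1-\rho}$ (any common scaling
gives the same ICC distribution), simulates $N$ matrices, and records the
central range of ICC(1). `icc_confint_simulated()` then reads the curves
horizontally: the lower confidence limit is the smallest $\rho$ whose
upper central-range limit reaches the observed sample ICC, the upper limit
the largest $\rho$ whose lower central-range limit does not exceed it,
with linear interpolation between grid points — the numerical equivalent
of reading central-range diagrams by eye. Defaults are a grid of 0 to 0.99
in steps of 0.01 with $N = 10000$ per point (under a minute for one curve
on a single core; curves are returned as objects precisely so they can be
reused across queries). The same curves serve ICC(C,1), whose distribution
is bias-invariant; they do *not* serve ICC(A,1). Limitations: the grid
tops out at 0.99, so an observed ICC very close to 1 returns an upper
limit capped at the grid edge, and resolution below the grid step cannot
be claimed. Within those limits the simulated intervals agree with the
analytic F-based ones to about ±0.03 for $n \ge 10$, which the tests
verify.

## What the generator does and does not emulate

The synthetic matrices are exactly Gaussian, additive, homoscedastic and
complete — the assumptions of the estimators, on purpose: the simulator's
role is to show the sampling behaviour of the estimators *under their own
model*, so passing tests certify the estimation machinery, not robustness.
Real reliability data can violate all four assumptions (floor and ceiling
effects, heteroscedastic noise, rater-by-subject interactions, dropout),
and nothing here quantifies behaviour under such violations. Likewise the
bundled clinical example is a fixed 10 × 3 matrix; the moderate ICC it
yields (≈ 0.71 with a wide interval) is a reminder that ten subjects give
only a coarse reliability estimate.

## Known limitations

Only the single-score coefficients are implemented: the average-score
forms ICC(·,k) are out of scope, as are unbalanced or incomplete designs,
confidence intervals for the variance components themselves, and
non-Gaussian generative models. The tidyverse-facing shape of the package
— tibble returns, `tidy()`/`glance()` methods, `autoplot()` — is a design
choice to make the per-replicate draws directly pipeable into dplyr and
ggplot2 workflows.
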