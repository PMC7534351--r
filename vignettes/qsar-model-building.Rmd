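---
title: "Small-n QSAR model building: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-n QSAR model building: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarforge)
```

## The problem

Classical QSAR works with very small samples: a chemical series of 9–30
compounds, each described by tens to hundreds of software-computed
molecular descriptors, and a potency response (pIC50, the negative
log10 of molar IC50). Two things dominate such an analysis: the danger of
chance correlation when descriptors outnumber compounds, and the need for
diagnostics that a bench chemist can compare across papers. qsarforge
implements the standard answer — multiple linear regression on a small,
explicitly selected descriptor subset, validated by leave-one-out
cross-validation — together with the selection machinery (all-subsets and
genetic-algorithm search) and the potency/selectivity arithmetic that
surrounds such models in kinase-inhibitor work.

## Model and diagnostics

`fit_mlr()` fits

$$\mathrm{pIC50}_i = \beta_0 + \sum_{j=1}^{p} \beta_j x_{ij} + \varepsilon_i$$

by QR least squares (no explicit matrix inverse; rank decided at a
relative tolerance of 1e-10, with an error naming the collinear columns).
Descriptors are never standardised: coefficients stay on raw descriptor
scales, directly comparable with published equations. An intercept is
always included. Construction requires n ≥ p + 2 so that the residual
degrees of freedom n − p − 1 support the standard error of estimate

$$s = \sqrt{\mathrm{RSS}/(n-p-1)}$$

and the F-statistic, which we compute as
$F = \frac{R^2/p}{(1-R^2)/(n-p-1)}$ — algebraically MSR/MSE; the tests
assert that identity to 1e-10.

Leave-one-out cross-validation (`loo_cv()`) reports
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$ with two conventions worth
stating because the literature does not always do so:

* **TSS is taken about the mean of the full training response**, not
  fold-wise means. This is the common QSAR convention and makes
  $Q^2 \le R^2$ and $\mathrm{PRESS} \ge \mathrm{RSS}$ hold identically,
  both asserted as universal properties in the test suite.
* The default implementation is the **hat-matrix shortcut**
  $e_i/(1-h_{ii})$, which for linear least squares equals the explicit
  refit loop exactly. The explicit loop is also implemented
  (`method = "refit"`) and the two are compared on 100 random datasets in
  the tests, at 1e-10 relative tolerance. Leverages at 1 (a compound that
  uniquely determines a coefficient) make the fold rank deficient and are
  an error, not a silent division.

LOO needs n ≥ p + 3 so every fold retains a fittable model.

## Prediction bands

`prediction_band()` provides the classical t-based intervals drawn on
experimental-versus-predicted plots: for a descriptor row $x_0$, the mean
response interval $\pm t_{1-\alpha/2,\,n-p-1}\, s\sqrt{x_0'(X'X)^{-1}x_0}$
and the new-observation interval with the extra unit of variance,
$\pm t\, s\sqrt{1 + x_0'(X'X)^{-1}x_0}$. The prediction band is strictly
wider pointwise whenever s > 0. How published figures construct their
bands is rarely stated; we use and label these classical forms. An
interpolating fit leaves rounding-level residuals rather than exactly zero
ones, so s below 1e-10 of the response scale is treated as zero: the bands
collapse to zero width and a warning flag is attached instead of
propagating numerical noise into the quantiles.

## Descriptor selection

`exhaustive_search()` enumerates every subset up to `max_size` (guarded at
one million subsets) and ranks by fitness — leave-one-out Q² by default,
R² as an option — with a deterministic tie-break: fitness descending, then
smaller subsets, then lexicographic on the joined names. Infeasible
subsets (rank deficient, or too large for the degrees of freedom) carry a
−Inf fitness sentinel rather than aborting a search.

`ga_search()` handles pools where enumeration is impractical. The
chromosome is a binary inclusion mask over the pool, constrained to at
most `max_subset_size` active bits. Defaults follow the selection protocol
of the bundled study — population 800, 3000 generations, mutation rate
0.6 — with the operator details, which that protocol leaves open, chosen
as standard: tournament selection of size 2, uniform crossover at rate
0.9, elitism 1, and initial masks holding between 2 and `max_subset_size`
active bits. One interpretation deserves emphasis: a *per-bit* flip
probability of 0.6 would randomise chromosomes faster than selection could
act, so the 0.6 is implemented as the probability that an offspring
undergoes a single random bit flip. Offspring violating the size cap are
repaired by clearing random excess bits; empty masks get one random bit.
Fitness values are memoised by mask, so the true cost is bounded by the
number of distinct subsets visited, and the whole trajectory is
bit-identical for a given seed. The subset-size cap defaults to 4, the
largest model size in the bundled study.

No collinearity pre-filter is applied by default; an optional pairwise
|r| guard (`max_cor`) can declare strongly collinear subsets infeasible.

Whether the bundled study's published subsets are the global optima of its
original ~128-descriptor pool cannot be decided from the six printed
descriptors; the tests therefore assert agreement between the search and
an independent brute-force oracle, not recovery of the published subsets —
though on the printed six-descriptor pool the all-subsets search does rank
{IW1, FLEX} first for the RAF1 response.

## The synthetic generator

`synthetic_spec()` + `simulate_qsar_dataset()` generate the structure the
analysis assumes, so every stage is testable without external data: an
equicorrelated Gaussian descriptor pool (one shared latent factor;
`correlation` sets the common pairwise r), a planted linear response on a
known active subset, and Gaussian residual noise. Two scale regimes exist:

* `scales = "descriptor"` rescales columns to ranges mimicking real
  descriptor families (INTEGY-moment-sized 0.01–0.05 through polar-surface
  -area-sized 99–137), for realistic-looking pools;
* `scales = "unit"` (default) keeps columns at mean 0, sd 1. The
  parameter-recovery study uses this regime because its criterion compares
  coefficient error against 2·noise_sd/√n, which is dimensionally
  meaningful only when descriptor and response scales match.

Noise is calibrated analytically, not by simulation: the planted signal
variance is $\beta'\Sigma\beta$ with $\Sigma$ the equicorrelated
covariance on the generated scales, and `calibrate_noise()` solves
$R^2 = \sigma_s^2/(\sigma_s^2+\sigma^2)$ for the residual sd. The default
regime mirrors the bundled study: n = 22 compounds, a pool of p = 20
descriptors with 4 active, true R² = 0.9 (the weaker of the two published
fits; the stronger is ≈ 0.97).

What the generator does **not** emulate: real descriptor distributions are
skewed, discrete (pharmacophore counts), and block-correlated rather than
equicorrelated, and real structure–activity relationships are only locally
linear. Passing recovery tests therefore demonstrates that the machinery
is correct under its own assumptions, not that any particular chemical
series satisfies them.

## Validation study sizes

The test suite exercises: 100 random datasets for the hat-vs-refit LOO
identity; 20 seeded trials of GA-versus-exhaustive agreement on p = 12
pools (subset cap 4, population 80, 60 generations — ample for a 793-subset
space with memoisation); and a 20-replicate recovery suite at the default
n = 22, p = 20 regime, where exhaustive selection at cap 4 recovers the
planted quadruple and the 20-seed mean coefficient bias sits two orders of
magnitude below the 2·noise_sd/√n criterion. These sizes keep the full
suite under a minute for the deterministic parts and under five minutes in
total.

## Numerical and interface choices

* Internal concentration unit is molar everywhere; the bundled CSVs store
  IC50 in nM (as printed) with explicit unit-bearing column names,
  converted on load. This avoids silent 10⁹ errors.
* Missing-response sentinels on read: "–", "-", "", "NA", "ND".
* Display conventions: pIC50 at 3 decimals, selectivity ratios at 2 — both
  are formatting only; all arithmetic is unrounded. The bundled 856.85 =
  838/0.978 fold-ratio confirms the unrounded-input convention.
* Panel hit summaries use ≥ threshold by default; `strict = TRUE` gives
  the strictly-greater semantics of "more than X%" screening rules.
  Percent inhibition is never clamped (slightly negative values are real
  assay read-outs).
* `run_reference_analysis()` is fully deterministic (no RNG) and verifies
  fixture MD5 checksums and IC50↔pIC50 transcription consistency before
  fitting; reruns are byte-identical.
* The published equations are reproduced from descriptors printed at 3
  decimals; refitting cannot recover the original unrounded fit exactly,
  and the package's refits agree with the published statistics within the
  slack that rounding induces (e.g. R² 0.9696 vs 0.972 for the RAF1
  model).

## Known limitations

Single-response OLS only: no PLS latent-variable modelling, no
regularisation, no applicability-domain machinery beyond leverage, and no
descriptor computation from structures — descriptor values are inputs.
Q² here is leave-one-out only; external test-set validation, y-scrambling
and bootstrap are out of scope.
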