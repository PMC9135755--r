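---
title: "Testing developmental trade-offs with allometric controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing developmental trade-offs with allometric controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomtrade)
```

## The problem

A recurring claim in evolutionary morphology is that two structures sharing
a developmental origin — such as the eye and the antenna, which both arise
from the eye-antennal imaginal disc in flies — are locked in an allocation
trade-off: enlarging one must shrink the other. The tempting summary
statistic is a ratio of the two trait sizes. But a ratio `y/x` presumes
isometry: under the allometric model `log(y) = beta * log(x) + alpha`, any
`beta != 1` makes the ratio covary with overall size, so species ranked by
a ratio may simply be ranked by body size. `ratio_scenarios()` makes the
deeper problem concrete: a trade-off, a pure increase of the numerator, and
a pure decrease of the denominator can all produce exactly the same ratio.

This package implements the alternative: model both traits on the log
scale, control allometry explicitly, and test association *conditional on
size* — between species (with phylogenetic regression) and within species
(with grouped standardized major axis fits).

## Models

### Phylogenetic regression (PGLS with Pagel's lambda)

Between-species observations are not independent: closely related species
inherit similar trait values. Under Brownian trait evolution the expected
covariance of two species equals the length of their shared root-to-ancestor
path, assembled by `bm_covariance()`. `pgls()` fits
`beta_hat = (X'V^-1 X)^-1 X'V^-1 y` with `V(lambda)` equal to that matrix
with off-diagonals multiplied by Pagel's `lambda` in `[0, 1]`: `lambda = 0`
is an ordinary regression on a star phylogeny, `lambda = 1` pure Brownian
structure, and intermediate values attenuate phylogenetic signal in the
residuals. `lambda` is profiled out by maximizing the restricted likelihood
(REML default — the residual variance is less biased at the sample sizes
comparative datasets have; a full-ML switch exists) with a golden-section
search on `[0, 1]` at tolerance 1e-6. Because the numeric optimizer cannot
land exactly on a boundary, a candidate boundary value whose likelihood is
at least as high replaces the interior iterate, so pure-Brownian or
star-like data report `lambda` of exactly 1 or 0.

Standard errors use `sigma2 = RSS_gls / (n - p)` and t tests on `n - p`
degrees of freedom, where `p` counts mean parameters; every fit records the
rows actually used, since rows with missing values are dropped per model,
not globally. Residuals are returned on the ordinary (untransformed)
response scale, because the downstream residual-association stage re-enters
a phylogenetic regression that itself accounts for the covariance;
whitening them twice would double-count phylogeny. Fixed-`lambda` fits
agree with `nlme::gls` + `ape::corPagel` to machine precision, which the
test suite asserts.

### The trade-off tests

`conditional_association()` fits `y ~ size + x`: the partner-trait
coefficient, given the control, is the trade-off test. A negative,
significant coefficient is consistent with allocation trade-offs; a
positive one indicates concerted variation. `residual_association()` is the
two-stage version — each focal trait regressed on the control, then
residuals regressed on residuals with the same engine — which estimates the
same conditional relationship while matching the way such results are
plotted. `ratio_size_test()` closes the loop by showing when a ratio
retains size signal (the log ratio regressed on log size, or on the
numerator itself, since a numerator that dominates the ratio also drives
its correlations).

### Grouped SMA: slopes, elevations, pairwise shifts

Within species, both variables carry biological variation, so ordinary
regression attenuates slopes; the standardized major axis
`b = sign(s_xy) * sqrt(s_yy / s_xx)` treats the axes symmetrically.
For several species the questions are ordered: do they share a slope, and
if so, do their elevations (intercepts at the common slope) differ?

- The common slope maximizes the grouped SMA profile likelihood. Writing
  `r_i(b) = var(y - b x)` and `f_i(b) = var(y + b x)` per group, the
  profile deviance is `sum_i w_i * log(r_i(b) f_i(b) / b^2)` (the `b^-2`
  term is the Jacobian of the rotation to residual/fitted axes). It is
  minimized by one-dimensional numerical optimization on the log-slope
  scale (tolerance 1e-8) — equivalent to, and more robust than, the
  classical fixed-point iteration. The homogeneity test compares this at
  the common versus the per-group slopes against chi-square on `g - 1` df.
- Elevations are `a_i = ybar_i - b_c * xbar_i`, with
  `var(a_i) = s2_res,i / n_i + xbar_i^2 var(b_c)` and covariances
  `xbar_i xbar_j var(b_c)`; `var(b_c)` comes from the observed information
  (numerical second derivative) of the profile likelihood. Equality is
  tested by the Wald quadratic form on `g - 1` df; pairwise tests use
  `df = 1`, by default re-estimating the common slope per pair (a flag
  reuses the global slope instead).
- Weighting: the profile uses per-group weights `n_i - 2` (residual
  degrees of freedom) rather than `n_i`, and residual variances use
  denominator `n_i - 2`. These choices were fixed by simulating the null —
  six groups of 30 sharing a line — and checking that the likelihood-ratio
  statistic and the Wald statistic match their nominal chi-square
  references: observed mean Wald statistic 5.05 (reference 5), type-I
  rates 5.2% and 4.7% at nominal 5%. The acceptance suite re-runs this
  calibration at 1000 replicates.

`pairwise_elevation()` assembles the antisymmetric matrix of elevation
differences and the symmetric matrices of Wald statistics and p-values
(Holm-adjusted values are emitted alongside raw ones; raw values drive the
default classification so that the package does not silently change the
inference convention of the field). `classify_shifts()` joins two such
matrices — one per structure, both against the same control — and labels
each species pair, in this order: **minor** when either structure's shift
is below `min_shift` (default 0.1 log units, the conventional cut for a
meaningful grade shift); **inverse** when the structures shift in opposite
directions with both shifts at least `min_shift`; **single_structure**
when exactly one structure's pairwise test is significant;
**same_direction**; **none**. Whether "inverse" should additionally demand
significance in *both* structures is genuinely ambiguous in practice, so
the default counts sign-plus-magnitude only and a `strict` flag adds the
dual-significance requirement; both counts are always reported, and since
the minor-exclusion is applied first, applying it before or after the sign
check yields the same tally (both orderings are represented in the
returned counts). `elevation_diff_correlation()` correlates the two
matrices' upper triangles; its output is permanently tagged exploratory
because the `g(g-1)/2` pairs share species and are not phylogenetically
independent.

## The synthetic-data generator

`simulate_species_traits()` generates log size by Brownian motion on a
depth-normalized tree, then
`log A = alpha_A + beta_A * log size + eps_A` (and likewise B) with
`(eps_A, eps_B)` correlated at `rho`. In the default *phylogenetic*
residual mode the deviations themselves evolve as bivariate Brownian
motion, so a simulated trade-off is heritable along the tree — the natural
reading of a conserved developmental constraint; an *independent* mode
separates tip-level from phylogenetic signal. Sub-seeds are derived per
component (size, deviations, individuals) so adding one trait does not
perturb the draws of another, and identical configs and seeds give
bit-identical serialized tables.

Default study conditions (chosen once, as the conditions all validation
runs under): 59 species; allometric slopes 0.75; residual sd 0.1 log10
units; Brownian rate 0.05 for log size on a depth-1 tree, i.e. a tip sd of
about 0.22 log10 units — roughly the genus-wide spread needed for
allometric structure to dominate measurement-scale noise; `rho = -0.7` for
the strong-trade-off preset; numerator slope 1.3 for the hyper-allometric
ratio-trap preset; six species with 4–8 individuals for the
individual-level presets. `preset_scenarios()` packages these.

What the generator does *not* emulate: measurement error beyond additive
log-scale noise, non-Brownian evolution (selection regimes,
Ornstein–Uhlenbeck pull, rate shifts), within-species allometric slope
variation, or the segmentation process behind real morphometrics. Passing
tests therefore demonstrate that the estimators and tests behave correctly
under their own assumptions — not that those assumptions hold for any
particular empirical dataset.

## Numerical choices and degenerate inputs

- Log transforms default to base 10 (a config switch gives natural logs);
  slopes, t, F and Wald statistics are invariant to the common base, and
  intercepts scale by `ln 10`, which the tests assert. The base is recorded
  on every table, and `raw_values()` back-transforms exactly.
- Exactly collinear groups (zero SMA residual variance) are handled by
  clamping the likelihood's variance terms at a relative floor of 1e-14:
  groups sharing a line report a null statistic, genuinely different
  noiseless slopes report an overwhelming one.
- Zero covariance between x and y makes the SMA slope sign undefined; it is
  set positive with a warning.
- `anova_term()` compares nested phylogenetic fits under the *full* model's
  fitted covariance, so the F statistic isolates the mean structure.
- Groups with `n = 3` are accepted but flagged `minimal_n`.

## Known limitations

- The chi-square references for the common-slope and elevation tests are
  asymptotic. At 30 observations per group they are well calibrated (see
  above); at 4–8 individuals per species — the realistic size of
  intraspecific neuroanatomy datasets — both tests become anticonservative
  (simulated type-I error roughly 7% and 15% at nominal 5% for n = 6).
  Pairwise shift classifications at such sample sizes should be read as
  descriptive, and the package deliberately reports effect sizes (the
  delta matrices) alongside the tests.
- PGLS here is maximum-likelihood with Pagel's lambda; studies fitted by
  MCMC will agree only approximately, and reproduction of such published
  values is expected within estimator tolerance, not to the printed digit.
- The elevation-difference correlation inherits the non-independence of
  shared species; it is reported with that caveat attached and no p-value.
- Validation problem sizes (500 replicates for slope recovery and the
  framework contrast, 1000 for null calibration, 200 for lambda recovery)
  were chosen to make Monte-Carlo error small relative to the tolerances
  asserted, while keeping the full suite runnable in minutes on one CPU.
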