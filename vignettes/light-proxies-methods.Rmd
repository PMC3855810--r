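---
title: "Light-availability proxies for tropical tree demography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-availability proxies for tropical tree demography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Light is the resource most often invoked to explain demographic
differences among co-occurring tropical tree species, but it is also the
hardest to measure at the scale of a whole census plot. `treelight`
implements two proxies and the machinery to compare them:

* a **canopy index (CAI)** — the estimated fraction of full irradiance
  at a point, derived from presence/absence censuses of vegetation in
  six height layers on a 5 m grid; and
* **neighborhood competition indices (NCI)** — sums of
  `dbh^alpha / dist^beta` over taller neighbors within 30 m, computable
  from the stem positions and diameters that nearly every census plot
  records.

Either proxy can drive two hierarchical Bayesian models: per-cell
recruit counts (negative binomial) and per-tree diameter growth
(lognormal process error with a measurement-error mixture). The package
also ships a synthetic stand generator so that the full workflow is
testable with known ground truth: real canopy-census data are rare and
the relevant tropical census datasets are access-restricted.

# Data preparation rules

Census snapshots hold all stems of at least 10 mm dbh with positions and
species. Analyses of cell-level quantities are restricted to a core
region obtained by stripping a 30 m margin from each plot side, so that
every focal point has its full 30 m neighborhood observed; a 1000 x
500 m plot with 5 m cells therefore yields 188 x 88 = 16,544 cells.
Cells are half-open, so each position belongs to exactly one cell.

*Recruits* are stems absent (or dead) in one census and alive with dbh
of at least 10 mm in the next — stems that crossed the 1 cm inclusion
threshold during the interval. They are counted per core cell and
species. *Growth* is the annualized dbh increment of stems alive in both
censuses, using only the main stem of multi-stem trees and excluding
palms (no secondary growth) and stems whose point of measure moved or
that broke and resprouted. Negative increments are kept: they are
informative about measurement error. An optional rounding rule floors
diameters below 55 mm to the nearest 5 mm in *both* censuses before
differencing, emulating intervals in which the earlier census recorded
small stems rounded down; applying it to both sides avoids a systematic
bias from comparing a floored with an unfloored value.

Species abundance — the covariate of the community-level models — is the
count of living conspecifics in the *whole* plot at interval start.
Margin trees are excluded from recruit counts but included in abundance:
abundance is a property of the plot population, not of the core sample.

# The canopy index

A **shade index** at a focal point is a weighted sum over occupied
layer-cells that lie fully above the point (layer lower bound at or
above the reference height) and closer than 20 m horizontally. The
default horizontal kernel is `1/(1 + d)` and all layers receive unit
weight. Published shade indices weight layers and distance in
site-calibrated ways that are not portable; our defaults are the
simplest monotone choice and every component is configurable. Grid cells
are evaluated at 2 m height — the height a recruit must surpass — and
trees at their allometric crown top.

Shade is unitless, so it is converted to irradiance by **quantile
matching**: the shade value at empirical quantile `q` (plotting position
`(rank - 0.5) / n`, average ranks for ties) maps to the `1 - q` quantile
of a reference irradiance distribution. Plotting positions keep mapped
values strictly inside the reference support; ties share a value. The
default reference is a lognormal truncated at 1 with median 2% of full
irradiance and log-sd 1, a synthetic stand-in (so labelled) for direct
understorey measurements, which are site-specific; it is configurable.
The calibration is fitted on the 2 m cell shades of each yearly census
and then applied, by monotone interpolation, to tree-crown shades of the
same year; yearly canopy indices are averaged arithmetically over a
census interval. A tree towering above every occupied layer has zero
shade and receives the maximum index — full light, not an error.

# Neighborhood competition indices

`NCI(alpha, beta) = sum_j dbh_j^alpha / max(dist_ij, 0.1 m)^beta` over
alive neighbors within 30 m that are taller (allometrically) than the
focal height. `dbh` enters in cm, distance in m; `0^0` counts as 1, so
`alpha = beta = 0` simply counts qualifying neighbors. The 0.1 m
distance floor prevents a neighbor arbitrarily close to a cell center
from dominating the sum; the exact value is configurable and matters
only in that degenerate case. For grid cells the focal height is the
2 m reference height (the same height at which recruits experience
light); for trees it is the tree's own height, and the tree is excluded
from its own neighborhood. "Taller than the focal point" for cells is
operationalized against the 2 m reference because recruits are the
smallest individuals in the community.

The exponents are chosen by a **grid search**: `alpha` and `beta` each
range over 0 to 3 in steps of 0.2 (256 combinations), and the pair
maximizing the absolute pooled Pearson correlation between NCI and
log(CAI) across census intervals is selected. The correlations are
negative — more competition, less light — which is why the criterion is
the absolute value. Ties break toward smaller `alpha`, then smaller
`beta`; exponent pairs with zero NCI variance are excluded.

Because the demographic models interpret their light coefficient on the
log-irradiance scale, the selected NCI is converted to the log(CAI)
scale by **median quantile regression with zero intercept**:
`logCAI ~ b1 * NCI` for cells, plus a quadratic term `b2 * NCI^2` for
trees, where the relationship is curved. The intercept is forced to
zero so that an empty neighborhood (NCI = 0) maps to 100% irradiance.
The median (rather than the mean) is used because extreme NCI values —
one large tree next to a focal point — act as outliers. The L1 problem
is solved by iteratively reweighted least squares polished with a direct
minimization of the objective (tolerance below 1e-8); for the linear
case the solution equals the weighted median of elementary slopes, which
the test suite uses as an independent oracle. Interval-specific
regressions give `NCI_ts`; pooling both intervals gives the general
`NCI_tg`. Converted values may fall below the observed log(CAI) range:
extreme NCI outliers legitimately map to extremely low light.

# Demographic models

Both models are hierarchical: species parameters are draws from
community-level regressions on log abundance, which shares strength with
the many rare species while letting data-rich species speak for
themselves. All light predictors are centered at fit time and the
centering constant is stored with the fit, so intercepts are "at mean
light" and shifting the light scale moves intercepts but not light
responses.

**Recruitment.** The expected count of species `j` in cell `i` is
`exp(a_j + b_j * x_i)` with `x_i` the centered log light — a power
function of light. Counts are negative binomial with species clumping
`k_j` (variance `mu + mu^2/k`), absorbing the spatial aggregation that
seed dispersal and habitat structure add on top of light. Priors:
`k_j ~ Uniform(0, 100)` (beyond `k = 10` the distribution is already
effectively Poisson, so the upper bound is innocuous) and flat
hyperpriors with positivity constraints on the spread parameters.
`b_j` classifies the light response: negative (`b < 0`), decelerating
(`0 < b < 1`), linear (`b = 1`), accelerating (`b > 1`). This reading
requires light on the log(CAI) scale; the package refuses to classify
fits on raw NCI values.

**Growth.** Predicted growth of tree `i` of species `j` is
`exp(a_j + b_j * x_i + c_j * log(dbh_i / 50))` mm/yr — a power function
of light and initial size, with dbh centered on 50 mm so `a_j` is the
log growth of a 50 mm tree at mean light. The *latent true growth* is
lognormal around this prediction with species log-sd `d_j` (the
biological process error; the lognormal makes the spread scale with the
prediction and puts the distribution's median exactly at the
prediction). The *observed* growth adds a two-component Normal
measurement-error mixture: a routine error with sd `0.927 + 0.0038 *
dbh` mm and a gross error with sd 25.6 mm affecting a fraction
`f = 0.027` of records; both sds divide by the interval length on the
annualized scale. The routine/gross sd values follow published dbh
remeasurement-error estimates for tropical censuses and are fully
configurable. `d_j` varies lognormally across the community with
hyperparameters `(delta1, delta2)`; their defaults (median 0.7, log-sd
0.3) are the package's own choice of a realistic community, as community
values are site-specific. Latent true growth is explicit in the model
(one parameter per tree, initialized at `max(obs, 0.05)` mm/yr); a
quadrature marginalization over the latent is provided only as a test
oracle.

The hyper-model covariate is the natural log of abundance with a Normal
link; with the default recruitment hypers (intercept regression
`-10.59 + 0.78 ln(abun)`, sd 0.97; light-response regression
`1.60 - 0.15 ln(abun)`, sd 0.67) this yields plausible per-cell
recruitment rates across the abundance range, which is why `ln` rather
than `log10` was adopted where the source material leaves the base
implicit.

# MCMC

The engine is Metropolis–Hastings with Gaussian random-walk proposals
and per-parameter step sizes. The recruitment model uses a full scan
(every parameter updated each iteration); the growth model uses sweeps
in which species-parameter families, all latent true growths, and the
hyperparameters are updated in turn. Within a family, species are
conditionally independent given the hyperparameters (and latents given
the species parameters), so proposing all of them at once and accepting
element-wise is the same sampler as a one-at-a-time scan — just
vectorizable. A literal single-site sampler (`single_site_scan()`) is
part of the engine and validated against closed-form targets.

Step sizes adapt during burn-in toward a target acceptance rate of 0.25,
every 50 iterations, and are frozen afterwards so the sampling phase is
a valid fixed-kernel chain. The adaptation multiplier is
`exp(2 |rate - 0.25|)`: proportional adjustment is needed because
well-identified and essentially unidentified parameters (say, the
clumping `k` of a species with three recruits, whose conditional is
nearly flat over (0, 100]) need step sizes several orders of magnitude
apart, and a fixed small multiplier cannot bridge that range within a
1000-iteration burn-in.

Defaults follow the models' historical practice: recruitment runs two
chains with different initial values (`b` starting at 0 and at 1),
burn-in 1000 and 6000 samples, with convergence monitored by the
Gelman–Rubin potential scale reduction factor (values below 1.1 pass;
the statistic is floored at 1). Growth runs longer per-parameter updates
through sweeps (desk defaults 2000 + 2000 sweeps; every parameter is
visited once per sweep). Posterior summaries are means with central 95%
credible intervals using linearly interpolated order statistics (the
convention matters: draws `1..100` give interval (3.475, 97.525)).

# The synthetic stand generator

The generator emulates the stand structure the indices were designed
for: ~32 m²/ha basal area and a 33 m canopy. Species abundances follow
a log-series (shape 0.98); diameters are 10 mm plus a Weibull (shape
0.85, scale 55 mm), giving many small stems, a long right tail, and
about 4000 stems/ha at the target basal area; tree number is chosen to
hit the basal-area target within 10% (redrawn with an adjusted count
otherwise, with a bounded number of attempts). Positions are uniform by
default, with optional Thomas-process clustering (per-species parents
with Gaussian offspring scatter) as a stylized dispersal-limitation
pattern. Heights follow `1.5 * dbh_cm^0.7` m capped at the canopy
height; crowns are disks of radius `0.5 * dbh_cm^0.6` m spanning the top
30% of tree height. The crown model is explicitly *not* from any
published allometry — it is a configurable stylization, and the canopy
census generator marks a layer-cell occupied when a crown disk overlaps
the cell horizontally and the crown's vertical extent intersects the
layer.

Ground-truth demographic parameters are drawn from the community
hyper-models above, `k_j` uniform on (0, 100] truncated below at 0.05
(smaller values make negative-binomial draws numerically degenerate).
The latent light-field simulator draws canopy-index values whose logs
are Normal, truncated above at 0, with median 2% irradiance and log-sd
0.8 — the spread of understorey light in a closed canopy. Simulated
recruitment studies place species abundances uniformly on the log scale
between 50 and 8000 individuals, spanning rare to dominant.

What the generator does *not* emulate: asymmetric or displaced crowns,
interspecific allometric variation, soil-driven spatial autocorrelation,
multi-year light histories, or disturbance dynamics. Passing
parameter-recovery tests on these synthetic stands therefore
demonstrates that the estimation machinery is correct and calibrated —
not that the proxies would agree equally well on real forests, where
crown asymmetry is precisely one of the documented reasons the two
proxies diverge.

# Verification strategy and problem sizes

The test suite checks every stage against an independent oracle where
one exists: a brute-force O(n²) double loop for the bucketed NCI; the
weighted-median closed form for the zero-intercept L1 fit; closed-form
negative-binomial and lognormal identities; quadrature versus
Monte-Carlo marginals for the growth observation model; and closed-form
targets for both MCMC scan modes.

Parameter-recovery checks run at desk scale: recruitment with 60 species
on 2000 cells (two chains, burn-in 1000 + 6000 samples) and growth with
40 species on 5000 trees (3000 + 3000 sweeps). At these sizes the
light-response ranks correlate with truth above 0.7 and the chains
converge below the 1.1 threshold. Coverage of the hyperparameter
intervals is asserted allowing one miss per model: with 6 + 11
nominally-95% intervals, about 0.85 misses are expected from coverage
alone even for a perfectly calibrated sampler, and at 40–60 species the
realized community sample's own moments deviate from the generating
hyperparameters; demanding zero misses would reject a correct
implementation roughly half the time.

# Known limitations

* The growth sampler treats measurement-error parameters as known
  constants; they are configurable but not estimated.
* The exponent grid search optimizes the correlation with log(CAI), not
  with demography; species-specific exponent optimization is out of
  scope.
* Classification consistency across intervals inherits the
  low-information behaviour of CI-based classes: most species with few
  recruits are honestly "unclassified".
* The pipeline's synthetic canopy is generated from the same stand that
  provides the NCI neighbors, so synthetic NCI–CAI correlations are
  stronger and cleaner than field values; they exercise the machinery,
  not the ecology.
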