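# treelight

Light availability shapes recruitment and growth of tropical trees, but
direct light measurements at the scale of a census plot are infeasible.
Two proxies are in use: a **canopy index** (CAI) — the estimated
fraction of full irradiance derived from layered canopy-occupancy
censuses by quantile matching against a reference irradiance
distribution — and **neighborhood competition indices** (NCI), computed
from the stem positions and diameters that nearly every forest plot
records:

    NCI_i(alpha, beta) = sum_j dbh_j^alpha / dist_ij^beta

summed over neighbors `j` within 30 m that are taller than the focal
point (`dbh` in cm, distance in m). `treelight` implements both proxies
and the workflow to compare them: an `(alpha, beta)` grid search
against log(CAI), a zero-intercept median quantile regression that
converts NCI onto the log-irradiance scale, and hierarchical Bayesian
models of species-specific demography driven by either proxy —

* **recruitment**: per-cell counts `~ NegBin(exp(a_j + b_j x_i), k_j)`
  with clumping `k_j`, and
* **growth**: `exp(a_j + b_j x_i + c_j log(dbh/50))` mm/yr with
  lognormal process error and a two-component measurement-error
  mixture around latent true growth,

where `x_i` is centered log light and species parameters follow
community-level regressions on log abundance. The light-response
exponent `b_j` classifies each species (negative / decelerating /
accelerating). Both models are fitted by adaptive
Metropolis–Hastings MCMC with Gelman–Rubin convergence checks. A
synthetic stand generator (log-series abundances, ~32 m²/ha basal
area, 33 m canopy, configurable crown allometry) provides ground truth
for end-to-end parameter-recovery testing; restricted field data are
not required anywhere.

For whom: forest ecologists comparing light proxies across census
plots, and anyone needing a tested reference implementation of these
demographic models.

## Worked example

One synthetic census interval, canopy index, exponent search,
conversion, and a recruitment fit on counts simulated from known
parameters:

```r
library(treelight)

std    <- generate_stand(stand_config(plot_width = 180, plot_height = 180,
                                      richness = 12, seed = 7))
grid   <- partition_core(180, 180, margin = 15, cell_size = 5)
canopy <- generate_canopy_census(std)
cai    <- cai_for_cells(list(canopy), grid)
summary(cai$value)
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max.
#> 0.0007672 0.0101969 0.0199989 0.0326794 0.0392564 0.5097897

prof <- nci_profiles_for_cells(grid, std)
gs   <- nci_grid_search(list(list(profile = prof,
                                  log_light = log(cai$value))))
gs
#> <nci_grid_search> 256 combinations; best alpha = 3 , beta = 0.8 (pooled r = -0.522 )

nci  <- compute_nci(grid$centers$cx, grid$centers$cy, 2, std,
                    nci_config(gs$alpha, gs$beta))
conv <- fit_conversion(nci, log(cai$value), degree = 1)
exp(apply_conversion(conv, 0))   # empty neighborhood -> 100% irradiance
#> [1] 1

abun  <- compute_abundance(std)
truth <- draw_species_params(recruit_hypers(), abun, seed = 8)
rec   <- simulate_recruit_counts(truth, cai, seed = 9)
set.seed(10)
fit <- fit_recruitment(rec, cai, abun, n_chains = 2,
                       n_burn = 500, n_sample = 1500)
fit
#> <treelight_fit> recruitment model: 8 species, 2 chain(s) x 1500 draws
#>   max R-hat: 1.045

head(classify_species(fit), 4)
#>   species        mean         lo        hi   class_mean     class_ci
#> 1   sp001  0.81790996  0.4339197 1.2697093 decelerating unclassified
#> 2   sp002  0.61121755 -0.6978897 1.6115860 decelerating unclassified
#> 3   sp005  1.77341071  1.1278699 2.3269858 accelerating accelerating
#> 4   sp006 -0.06525059 -0.9221335 0.8207859     negative unclassified

b <- species_params(fit, "b")
cor(b$mean, truth$b_r[match(b$species, truth$species)])
#> [1] 0.8776381
```

Reading the output: the median cell receives ~2% of full irradiance
(closed canopy); the grid search picks the size/distance exponents most
correlated with log canopy index over all 256 combinations; the
zero-intercept conversion maps an empty neighborhood to exactly 100%
irradiance; the fitted light responses recover the simulated truth with
r = 0.88, and species are classified by posterior mean and — more
conservatively — by whether the whole 95% credible interval falls in
one response class. `run_pipeline()` chains these stages (including
interval-specific vs pooled conversions, classification-consistency and
cross-model agreement tables) from a single seeded configuration.

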