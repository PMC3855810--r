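# Shared fixture builders and independent oracles. Everything is built
# in code; heavy posterior fits used by several acceptance checks are
# computed once per test run and cached.

mk_trees <- function(tree_id, species_id = "spA", x = 50, y = 50,
                     dbh = 100, alive = TRUE, palm = FALSE,
                     main_stem = TRUE, stem_issue = FALSE) {
  data.frame(tree_id = tree_id, species_id = species_id, x = x, y = y,
             dbh = dbh, alive = alive, palm = palm,
             main_stem = main_stem, stem_issue = stem_issue,
             stringsAsFactors = FALSE)
}

mk_snapshot <- function(trees, year = 1985, w = 100, h = 100) {
  census_snapshot(trees, year, w, h)
}

# hand-built truth set (bypasses the hyper-model draw)
mk_recruit_truth <- function(species, a_r, b_r, k, abundance = 100) {
  out <- data.frame(species = species, abundance = abundance,
                    a_r = a_r, b_r = b_r, k = k,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_set", "data.frame")
  out
}

mk_growth_truth <- function(species, a_g, b_g, c, d, abundance = 100) {
  out <- data.frame(species = species, abundance = abundance,
                    a_g = a_g, b_g = b_g, c = c, d = d,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_set", "data.frame")
  out
}

# O(n^2) double-loop NCI oracle, written independently of the package's
# bucketed implementation
brute_nci <- function(x, y, focal_height, snapshot, config, allometry) {
  tr <- snapshot$trees[snapshot$trees$alive, ]
  hts <- tree_height(tr$dbh, allometry)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- 0
    for (j in seq_len(nrow(tr))) {
      d <- sqrt((tr$x[j] - x[i])^2 + (tr$y[j] - y[i])^2)
      if (d > config$radius) next
      if (config$taller_only && hts[j] <= focal_height[i]) next
      s <- s + (tr$dbh[j] / 10)^config$alpha /
        max(d, config$dist_floor)^config$beta
    }
    out[i] <- s
  }
  out
}

# exact zero-intercept LAD slope: the weighted median of the slopes
# y_i / x_i with weights |x_i| (piecewise-linear objective)
lad_slope_oracle <- function(x, y) {
  keep <- x != 0
  slopes <- y[keep] / x[keep]
  w <- abs(x[keep])
  ord <- order(slopes)
  cw <- cumsum(w[ord])
  slopes[ord][which(cw >= sum(w) / 2)[1]]
}

# simulated recruitment data set under the community hyper-model
# defaults; abundances span the range from rare to dominant uniformly on
# the log scale
sim_recruit_study <- function(S, n_cells, seed) {
  set.seed(seed)
  abun <- setNames(round(exp(runif(S, log(50), log(8000)))),
                   sprintf("sp%03d", seq_len(S)))
  truth <- draw_species_params(recruit_hypers(), abun, seed = seed + 1)
  lf <- simulate_light_field(n = n_cells, seed = seed + 2)
  rec <- simulate_recruit_counts(truth, lf, seed = seed + 3)
  list(abun = abun, truth = truth, lf = lf, rec = rec)
}

sim_growth_study <- function(S, n_trees, seed) {
  set.seed(seed)
  abun <- setNames(round(exp(runif(S, log(50), log(8000)))),
                   sprintf("sp%03d", seq_len(S)))
  truth <- draw_species_params(growth_hypers(), abun, seed = seed + 1)
  species <- sample(names(abun), n_trees, replace = TRUE, prob = abun)
  dbh0 <- 10 + rweibull(n_trees, 0.85, 55)
  lf <- simulate_light_field(n = n_trees, seed = seed + 2)
  recs <- simulate_growth_observations(truth, lf$value, species, dbh0,
                                       error_model(), 5, seed = seed + 3)
  tlf <- light_field(recs$tree_id, recs$light, scale = "cai", at = "tree")
  list(abun = abun, truth = truth, recs = recs, tlf = tlf)
}

# heavy fits shared across acceptance checks, computed once
.fit_cache <- new.env(parent = emptyenv())

cached_recruit_fit <- function() {
  if (is.null(.fit_cache$recruit)) {
    study <- sim_recruit_study(S = 60, n_cells = 2000, seed = 100)
    set.seed(101)
    fit <- fit_recruitment(study$rec, study$lf, study$abun,
                           n_chains = 2, n_burn = 1000, n_sample = 6000)
    .fit_cache$recruit <- list(study = study, fit = fit)
  }
  .fit_cache$recruit
}

cached_growth_fit <- function() {
  if (is.null(.fit_cache$growth)) {
    study <- sim_growth_study(S = 40, n_trees = 5000, seed = 200)
    set.seed(201)
    fit <- fit_growth(study$recs, study$tlf, study$abun, n_chains = 1,
                      n_burn = 3000, n_sample = 3000)
    .fit_cache$growth <- list(study = study, fit = fit)
  }
  .fit_cache$growth
}
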