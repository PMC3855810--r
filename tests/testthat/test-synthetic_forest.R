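test_that("stand generation is reproducible and hits the basal-area target", {
  cfg <- stand_config(seed = 42)
  s1 <- generate_stand(cfg)
  s2 <- generate_stand(cfg)
  expect_identical(s1$trees, s2$trees)
  # 1 ha plot at 32 m2/ha: realized basal area within 10%
  ba <- sum(pi * (s1$trees$dbh / 2000)^2)
  expect_lt(abs(ba - 32) / 32, 0.1)
  # richness bounded by the pool; rank-abundance curve decreases
  expect_lte(length(unique(s1$trees$species_id)), 60)
  expect_true(all(diff(sort(table(s1$trees$species_id),
                            decreasing = TRUE)) <= 0))
  expect_true(all(s1$trees$dbh >= 10))
  # an unattainable target (a single tree always overshoots) errors out
  expect_error(generate_stand(stand_config(plot_width = 5, plot_height = 5,
                                           basal_area = 0.1,
                                           richness = 1)),
               "attempts")
})

test_that("Thomas clustering concentrates conspecifics relative to uniform", {
  cfg_u <- stand_config(plot_width = 50, plot_height = 50, seed = 5,
                        richness = 5)
  cfg_c <- stand_config(plot_width = 50, plot_height = 50, seed = 5,
                        richness = 5,
                        clustering = list(parents_per_ha = 8, sigma = 3))
  nn_dist <- function(std) {
    tr <- std$trees
    sp <- names(which.max(table(tr$species_id)))
    pts <- tr[tr$species_id == sp, c("x", "y")]
    d <- as.matrix(dist(pts)); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  expect_lt(nn_dist(generate_stand(cfg_c)), nn_dist(generate_stand(cfg_u)))
})

test_that("canopy occupancy follows the crown geometry", {
  al <- allometry_config(h0 = 5, h1 = 0.01, r0 = 2, r1 = 0,
                         crown_depth_frac = 0.3)
  # a single ~5 m tree with a 2 m crown radius at a cell center
  snap <- mk_snapshot(mk_trees("t1", x = 7.5, y = 7.5, dbh = 10),
                      w = 15, h = 15)
  cc <- generate_canopy_census(snap, al)
  # crown spans [3.5, 5] m: only the 2-5 m layer, only the stem cell
  occ <- which(cc$layers, arr.ind = TRUE)
  expect_equal(nrow(occ), 1L)
  expect_equal(unname(occ[1, ]), c(2L, 2L, 2L))
  # empty stand: nothing occupied
  empty <- snap; empty$trees <- snap$trees[0, ]
  expect_false(any(generate_canopy_census(empty, al)$layers))
  # a taller stand reaches higher layers under the same crown model
  tall <- mk_snapshot(mk_trees("t1", x = 7.5, y = 7.5, dbh = 10),
                      w = 15, h = 15)
  al_tall <- allometry_config(h0 = 25, h1 = 0.01, r0 = 2, r1 = 0,
                              crown_depth_frac = 0.3)
  cc_tall <- generate_canopy_census(tall, al_tall)
  expect_gt(max(which(apply(cc_tall$layers, 3, any))),
            max(which(apply(cc$layers, 3, any))))
})

test_that("species parameters follow the abundance hyper-model", {
  abun <- setNames(rep(1000, 4000), paste0("s", 1:4000))
  truth <- draw_species_params(recruit_hypers(), abun, seed = 31)
  expect_equal(mean(truth$a_r), -10.59 + 0.78 * log(1000),
               tolerance = 0.02)
  expect_equal(sd(truth$a_r), 0.97, tolerance = 0.05)
  expect_true(all(truth$k > 0.05 & truth$k <= 100))
  # reproducible under the seed
  expect_identical(truth, draw_species_params(recruit_hypers(), abun,
                                              seed = 31))
  # zero-variance limit: parameters equal the regression line
  h0 <- recruit_hypers(sigma_alpha = 1e-12, sigma_beta = 1e-12)
  t0 <- draw_species_params(h0, abun[1:5], seed = 32)
  expect_equal(t0$a_r, rep(-10.59 + 0.78 * log(1000), 5), tolerance = 1e-9)
  # growth truth honors its own law
  tg <- draw_species_params(growth_hypers(), abun, seed = 33)
  expect_equal(mean(tg$b_g), 0.86 - 0.07 * log(1000), tolerance = 0.02)
  expect_equal(median(tg$d), 0.7, tolerance = 0.03)
})

test_that("latent light fields stay in (0, 1] and are reproducible", {
  lf <- simulate_light_field(n = 5000, seed = 41)
  expect_true(all(lf$value > 0 & lf$value <= 1))
  expect_identical(lf, simulate_light_field(n = 5000, seed = 41))
  expect_equal(median(log(lf$value)), log(0.02), tolerance = 0.15)
  flat <- simulate_light_field(n = 10, sd_log = 0, seed = 1)
  expect_equal(flat$value, rep(0.02, 10))
})

test_that("canopy-backed light fields delegate to the canopy index", {
  set.seed(42)
  std <- generate_stand(stand_config(plot_width = 50, plot_height = 50,
                                     richness = 6, seed = 43))
  cc <- generate_canopy_census(std)
  g <- partition_core(50, 50, 10, 5)
  lf <- simulate_light_field(mode = "from_canopy", censuses = list(cc),
                             grid = g)
  expect_equal(lf, cai_for_cells(list(cc), g))
  expect_error(simulate_light_field(mode = "nonsense"), "arg")
})

test_that("simulated recruit counts match the negative-binomial law", {
  # b = 0, large k: counts approximate Poisson(exp(a))
  truth <- mk_recruit_truth("s1", a_r = log(2), b_r = 0, k = 99)
  lf <- simulate_light_field(n = 20000, seed = 51)
  rec <- simulate_recruit_counts(truth, lf, seed = 52)
  Y <- as.matrix(rec)
  expect_equal(mean(Y), 2, tolerance = 0.05)
  expect_equal(var(as.numeric(Y)), 2 + 4 / 99, tolerance = 0.1)
  # k = 1, mean 1: half the cells are empty ((k/(k+mu))^k = 1/2)
  truth2 <- mk_recruit_truth("s1", a_r = 0, b_r = 0, k = 1)
  rec2 <- simulate_recruit_counts(truth2, lf, seed = 53)
  expect_equal(mean(as.matrix(rec2) == 0), 0.5, tolerance = 0.02)
  # NB variance inflation: var = mu + mu^2/k
  truth3 <- mk_recruit_truth("s1", a_r = log(3), b_r = 0, k = 0.8)
  Y3 <- as.numeric(as.matrix(simulate_recruit_counts(truth3, lf, seed = 54)))
  expect_equal(var(Y3), 3 + 9 / 0.8, tolerance = 0.6)
  # reproducible
  expect_identical(rec$counts,
                   simulate_recruit_counts(truth, lf, seed = 52)$counts)
})

test_that("simulated growth honors the lognormal median and error mixture", {
  # no measurement error: median(obs) equals the prediction
  em0 <- error_model(s0 = 1e-9, s1 = 0, sd2 = 1e-9, f = 0)
  truth <- mk_growth_truth("s1", a_g = log(1.2), b_g = 0, c = 0, d = 0.6)
  n <- 20000
  recs <- simulate_growth_observations(truth, rep(0.02, n),
                                       rep("s1", n), rep(50, n), em0,
                                       5, seed = 61)
  expect_equal(median(recs$obs_growth), 1.2, tolerance = 0.03)
  expect_equal(sd(log(recs$true_growth)), 0.6, tolerance = 0.02)
  # with a huge routine error observations can go negative
  em_big <- error_model(s0 = 30, s1 = 0, sd2 = 30, f = 0)
  recs2 <- simulate_growth_observations(truth, rep(0.02, 100),
                                        rep("s1", 100), rep(50, 100),
                                        em_big, 5, seed = 62)
  expect_true(any(recs2$obs_growth < 0))
  expect_true(all(recs2$true_growth > 0))
  # degenerate limits: obs equals the prediction exactly
  truth0 <- mk_growth_truth("s1", a_g = log(2), b_g = 0, c = 0, d = 1e-12)
  recs3 <- simulate_growth_observations(truth0, rep(0.02, 5), rep("s1", 5),
                                        rep(50, 5), em0, 5, seed = 63)
  expect_equal(recs3$obs_growth, rep(2, 5), tolerance = 1e-6)
})
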