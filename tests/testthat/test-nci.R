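test_that("NCI sums dbh^alpha / dist^beta over taller neighbors in radius", {
  al <- allometry_config()
  # one neighbor: dbh 100 mm (10 cm), 1 m from the focal point
  snap <- mk_snapshot(mk_trees("n1", x = 51, y = 50, dbh = 100))
  expect_equal(compute_nci(50, 50, 2, snap, nci_config(1, 1), al), 10)
  # alpha = beta = 0 counts qualifying neighbors (0^0 = 1)
  expect_equal(compute_nci(50, 50, 2, snap, nci_config(0, 0), al), 1)
  # neighbors shorter than the focal height do not count
  expect_equal(compute_nci(50, 50, 30, snap, nci_config(1, 1), al), 0)
  # ... unless the taller-only rule is off
  expect_equal(compute_nci(50, 50, 30, snap,
                           nci_config(1, 1, taller_only = FALSE), al), 10)
  # beyond the radius nothing counts
  expect_equal(compute_nci(50, 50, 2, snap,
                           nci_config(1, 1, radius = 0.5), al), 0)
  # the distance floor caps the contribution of coincident neighbors
  expect_equal(compute_nci(51, 50, 2, snap, nci_config(1, 1), al),
               10 / 0.1)
  # a focal tree never counts itself
  expect_equal(compute_nci(51, 50, 2, snap, nci_config(1, 1), al,
                           exclude = "n1"), 0)
  # focal points outside the core are rejected when a grid is given
  g <- partition_core(100, 100, 30, 5)
  expect_error(compute_nci(10, 50, 2, snap, nci_config(1, 1), al,
                           grid = g), "core")
})

test_that("size and distance exponents of 3 give eight-fold effects", {
  al <- allometry_config()
  cfg3 <- nci_config(3, 3)
  base <- compute_nci(50, 50, 2,
                      mk_snapshot(mk_trees("n1", x = 52, y = 50, dbh = 100)),
                      cfg3, al)
  double_dbh <- compute_nci(50, 50, 2,
                            mk_snapshot(mk_trees("n1", x = 52, y = 50,
                                                 dbh = 200)),
                            cfg3, al)
  double_dist <- compute_nci(50, 50, 2,
                             mk_snapshot(mk_trees("n1", x = 54, y = 50,
                                                  dbh = 100)),
                             cfg3, al)
  expect_equal(double_dbh / base, 8)
  expect_equal(base / double_dist, 8)
})

test_that("bucketed NCI equals the brute-force double loop on random stands", {
  al <- allometry_config()
  set.seed(11)
  trees <- mk_trees(paste0("t", 1:200), x = runif(200, 0, 120),
                    y = runif(200, 0, 120),
                    dbh = 10 + rweibull(200, 0.9, 60))
  snap <- mk_snapshot(trees, w = 120, h = 120)
  px <- runif(25, 30, 90); py <- runif(25, 30, 90)
  for (cfg in list(nci_config(1.6, 0.4), nci_config(0, 0),
                   nci_config(2.2, 3))) {
    expect_equal(compute_nci(px, py, 2, snap, cfg, al),
                 brute_nci(px, py, rep(2, 25), snap, cfg, al))
  }
})

test_that("NCI is translation-invariant and monotone in the neighbor set", {
  al <- allometry_config()
  set.seed(12)
  trees <- mk_trees(paste0("t", 1:50), x = runif(50, 40, 60),
                    y = runif(50, 40, 60), dbh = runif(50, 20, 500))
  snap <- mk_snapshot(trees)
  cfg <- nci_config(1.6, 0.4)
  v0 <- compute_nci(50, 50, 2, snap, cfg, al)
  shifted <- trees; shifted$x <- trees$x + 7; shifted$y <- trees$y - 3
  expect_equal(compute_nci(57, 47, 2, mk_snapshot(shifted), cfg, al), v0)
  # permuting neighbors changes nothing; removing one never increases
  expect_equal(compute_nci(50, 50, 2, mk_snapshot(trees[50:1, ]), cfg, al),
               v0)
  expect_lt(compute_nci(50, 50, 2, mk_snapshot(trees[-1, ]), cfg, al), v0)
})

test_that("grid search covers 256 combinations and recovers a planted optimum", {
  al <- allometry_config()
  set.seed(13)
  std <- generate_stand(stand_config(plot_width = 80, plot_height = 80,
                                     richness = 15, seed = 14))
  g <- partition_core(80, 80, 15, 5)
  prof <- nci_profiles_for_cells(g, std, nci_config(1, 1), al)
  planted <- compute_nci(g$centers$cx, g$centers$cy, 2, std,
                         nci_config(1.6, 0.4), al)
  log_light <- -0.001 * planted + rnorm(length(planted), 0, 0.001)
  gs <- nci_grid_search(list(list(profile = prof, log_light = log_light)))
  expect_equal(gs$n_combinations, 256L)
  expect_equal(c(gs$alpha, gs$beta), c(1.6, 0.4))
  expect_lt(gs$r_best, -0.99)
  expect_equal(dim(gs$r_pooled), c(16L, 16L))
  # the surface is deterministic given inputs
  gs2 <- nci_grid_search(list(list(profile = prof, log_light = log_light)))
  expect_identical(gs$r_pooled, gs2$r_pooled)

  # light unrelated to the stand: selection still unique via tie-break
  set.seed(15)
  noise <- rnorm(length(planted))
  gs3 <- nci_grid_search(list(list(profile = prof, log_light = noise)))
  expect_length(gs3$alpha, 1)
  expect_true(max(abs(gs3$r_pooled), na.rm = TRUE) < 0.3)
})

test_that("zero-intercept median regression recovers exact and noisy lines", {
  x <- 0:10
  conv <- fit_conversion(x, -0.05 * x, degree = 1)
  expect_equal(conv$b1, -0.05, tolerance = 1e-7)
  expect_equal(conv$b2, 0)

  # robust to symmetric heavy-tailed noise around the median line
  set.seed(16)
  xn <- runif(5000, 0, 10)
  yn <- -0.05 * xn + rcauchy(5000, 0, 0.1)
  convn <- fit_conversion(xn, yn, degree = 1)
  expect_equal(convn$b1, -0.05, tolerance = 0.01)
  # and matches the weighted-median closed form of the L1 problem
  expect_equal(convn$b1, lad_slope_oracle(xn, yn), tolerance = 1e-4)
  # about half the residuals are positive at the median fit
  resid <- yn - apply_conversion(convn, xn)
  expect_equal(mean(resid > 0), 0.5, tolerance = 0.03)

  # quadratic fit reproduces a noiseless parabola
  y2 <- -0.04 * x - 0.002 * x^2
  conv2 <- fit_conversion(x, y2, degree = 2)
  expect_equal(conv2$b1, -0.04, tolerance = 1e-5)
  expect_equal(conv2$b2, -0.002, tolerance = 1e-5)

  expect_error(fit_conversion(rep(2, 10), rnorm(10)), "degenerate")
})

test_that("conversion maps an empty neighborhood to full irradiance", {
  set.seed(17)
  x <- runif(100, 0, 50)
  conv <- fit_conversion(x, -0.03 * x + rnorm(100, 0, 0.2), degree = 1)
  expect_identical(apply_conversion(conv, 0), 0)   # log canopy index 0
  expect_identical(exp(apply_conversion(conv, 0)), 1)  # canopy index 1
  # monotone decreasing over the observed range when b1 < 0, b2 <= 0
  v <- apply_conversion(conv, sort(x))
  expect_true(all(diff(v) <= 0))
  # hand-evaluated polynomial for degree 2
  cv <- structure(list(b1 = -0.1, b2 = -0.01, degree = 2, tau = 0.5),
                  class = "nci_conversion")
  expect_equal(apply_conversion(cv, c(0, 1, 2)),
               c(0, -0.11, -0.24))
})
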