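test_that("growth prediction centers on 50 mm dbh", {
  expect_equal(predict_growth(0.3, 0.5, -0.2, x = 0, dbh = 50), exp(0.3))
  expect_equal(predict_growth(0, 1, 0, x = log(3), dbh = 50), 3)
  # c = 0: size-independent
  expect_equal(predict_growth(0.1, 0.5, 0, x = 0.2, dbh = c(10, 500)),
               rep(exp(0.1 + 0.1), 2))
  expect_error(predict_growth(0, 0, 0, 0, dbh = -5))
})

test_that("the observation mixture scales with interval length and normalizes", {
  em <- error_model()
  # f = 0 collapses to a single Normal
  em0 <- error_model(f = 0)
  expect_equal(obs_loglik(1.3, 1, dbh = 100, int = 5, em0),
               dnorm(1.3, 1, (0.927 + 0.0038 * 100) / 5, log = TRUE))
  # doubling the interval halves both sds
  expect_equal(obs_loglik(1.05, 1, dbh = 100, int = 10, em0),
               dnorm(0.05, 0, (0.927 + 0.0038 * 100) / 10, log = TRUE))
  # the density integrates to 1 over obs
  for (int in c(1, 5)) {
    total <- integrate(function(o)
      exp(obs_loglik(o, true = 1, dbh = 80, int = int, em)),
      -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("the process law is lognormal with median at the prediction", {
  # at true = pred the log density is -log(true * d * sqrt(2*pi))
  expect_equal(process_loglik(2, 2, 0.6), -log(2 * 0.6 * sqrt(2 * pi)))
  expect_identical(process_loglik(-1, 2, 0.6), -Inf)
  # median of draws equals the prediction
  set.seed(91)
  draws <- rlnorm(50000, log(1.7), 0.8)
  expect_equal(median(draws), 1.7, tolerance = 0.03)
  # d -> 0 concentrates mass at the prediction
  expect_gt(process_loglik(1.7, 1.7, 1e-4), process_loglik(1.8, 1.7, 1e-4))
  expect_lt(process_loglik(1.8, 1.7, 1e-4), -100)
})

test_that("quadrature marginal matches a Monte-Carlo marginal", {
  em <- error_model()
  set.seed(92)
  for (i in 1:10) {
    pred <- runif(1, 0.2, 4); d <- runif(1, 0.3, 1)
    dbh <- runif(1, 15, 300); int <- runif(1, 4, 6)
    obs <- rlnorm(1, log(pred), d) + rnorm(1, 0, 0.5)
    mc <- log(mean(exp(obs_loglik(obs, rlnorm(4e5, log(pred), d),
                                  dbh, int, em))))
    expect_equal(marginal_obs_loglik(obs, pred, d, dbh, int, em), mc,
                 tolerance = 0.05)
  }
})

test_that("the growth posterior composes its three likelihood layers", {
  recs <- data.frame(tree_id = "t1", species_id = "s1", dbh0 = 80,
                     obs_growth = 1.4, int = 5)
  em <- error_model()
  hyp <- growth_hypers()
  params <- list(a = 0.2, b = 0.6, c = -0.1, d = 0.5)
  lp <- growth_log_posterior(params, hyp, latents = 1.2, recs,
                             lnab = log(300), em, x = 0.3)
  pred <- predict_growth(0.2, 0.6, -0.1, 0.3, 80)
  by_hand <- obs_loglik(1.4, 1.2, 80, 5, em) +
    process_loglik(1.2, pred, 0.5) +
    dnorm(0.2, -0.06 - 0.06 * log(300), 0.48, log = TRUE) +
    dnorm(0.6, 0.86 - 0.07 * log(300), 0.16, log = TRUE) +
    dnorm(-0.1, -0.21 + 0.04 * log(300), 0.26, log = TRUE) +
    dlnorm(0.5, log(0.7), 0.3, log = TRUE)
  expect_equal(lp, by_hand)
  params$d <- -0.1
  expect_identical(growth_log_posterior(params, hyp, 1.2, recs,
                                        log(300), em, 0.3), -Inf)
  params$d <- 0.5
  expect_identical(growth_log_posterior(params, hyp, -1, recs,
                                        log(300), em, 0.3), -Inf)
})

test_that("a small growth fit recovers parameters and handles negatives", {
  study <- sim_growth_study(S = 10, n_trees = 800, seed = 93)
  expect_true(any(study$recs$obs_growth < 0))
  set.seed(94)
  fit <- fit_growth(study$recs, study$tlf, study$abun, n_chains = 1,
                    n_burn = 1200, n_sample = 1200)
  expect_s3_class(fit, "treelight_fit")
  a_est <- species_params(fit, "a")
  a_true <- study$truth$a_g[match(a_est$species, study$truth$species)]
  expect_gt(cor(a_est$mean, a_true), 0.8)
  d_est <- species_params(fit, "d")
  d_true <- study$truth$d[match(d_est$species, study$truth$species)]
  expect_gt(cor(d_est$mean, d_true), 0.5)
  # latent means are positive
  expect_true(all(fit$latent_mean > 0))
})

test_that("the growth posterior is invariant to record order", {
  study <- sim_growth_study(S = 5, n_trees = 60, seed = 99)
  recs <- study$recs
  x <- log(recs$light) - mean(log(recs$light))
  params <- list(a = rep(0.1, 5), b = rep(0.6, 5), c = rep(-0.1, 5),
                 d = rep(0.5, 5))
  lnab <- log(as.numeric(study$abun[sort(unique(recs$species_id))]))
  latents <- pmax(recs$obs_growth, 0.05)
  lp <- growth_log_posterior(params, growth_hypers(), latents, recs,
                             lnab, error_model(), x)
  perm <- sample(nrow(recs))
  lp2 <- growth_log_posterior(params, growth_hypers(), latents[perm],
                              recs[perm, ], lnab, error_model(), x[perm])
  expect_equal(lp2, lp)
})

test_that("an error-free fit recovers the process standard deviation", {
  set.seed(95)
  em0 <- error_model(s0 = 1e-4, s1 = 0, sd2 = 1e-3, f = 0)
  abun <- setNames(rep(1000, 4), paste0("s", 1:4))
  truth <- mk_growth_truth(names(abun), a_g = rep(0.1, 4),
                           b_g = rep(0.6, 4), c = rep(0, 4),
                           d = rep(0.5, 4), abundance = 1000)
  n <- 600
  species <- sample(names(abun), n, replace = TRUE)
  lf <- simulate_light_field(n = n, seed = 96)
  recs <- simulate_growth_observations(truth, lf$value, species,
                                       rep(50, n), em0, 5, seed = 97)
  tlf <- light_field(recs$tree_id, recs$light, scale = "cai", at = "tree")
  set.seed(98)
  fit <- fit_growth(recs, tlf, abun, em = em0, n_chains = 1,
                    n_burn = 1000, n_sample = 1000)
  d_est <- species_params(fit, "d")
  expect_true(all(d_est$lo < 0.5 & d_est$hi > 0.5))
  expect_equal(mean(d_est$mean), 0.5, tolerance = 0.1)
})
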