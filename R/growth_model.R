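# Hierarchical Bayesian model of annual dbh growth: a power function of
# light and initial size, lognormal process error around the prediction,
# a two-component Normal measurement-error mixture around the latent
# true growth, and abundance-dependent community regressions.

#' Predicted annual dbh growth
#'
#' `exp(a + b * x + c * log(dbh / 50))` in mm/yr: a power function of
#' light and initial diameter, with dbh centered on 50 mm so `a` is the
#' log growth of a 50 mm tree at mean light. `b` is the light-response
#' exponent (same interpretation as for recruitment) and `c` the size
#' exponent.
#'
#' @param a,b,c species parameters.
#' @param x centered log light.
#' @param dbh initial diameter in mm (> 0).
#' @return Predicted growth in mm/yr (> 0).
#' @export
predict_growth <- function(a, b, c, x, dbh) {
  stopifnot(all(dbh > 0))
  exp(a + b * x + c * log(dbh / 50))
}

#' Measurement-error model for dbh growth
#'
#' Two-component Normal mixture: a routine size-dependent error with
#' standard deviation `s0 + s1 * dbh` (slightly different placement of
#' the measuring tape) affecting most observations, and a large
#' size-independent error `sd2` (gross recording mistakes) affecting a
#' fraction `f` of them. Standard deviations apply to the dbh difference
#' and are divided by the interval length when the error is expressed on
#' the annualized scale. Defaults follow published dbh-remeasurement
#' error estimates for tropical censuses; `f = 0.027`.
#'
#' @param s0,s1 routine error: sd in mm at dbh 0 and slope per mm dbh.
#' @param sd2 gross-error sd in mm.
#' @param f fraction of observations affected by the gross error.
#' @return An object of class `error_model`.
#' @export
error_model <- function(s0 = 0.927, s1 = 0.0038, sd2 = 25.6, f = 0.027) {
  stopifnot(s0 > 0, s1 >= 0, sd2 > 0, f >= 0, f < 1)
  structure(list(s0 = s0, s1 = s1, sd2 = sd2, f = f),
            class = "error_model")
}

#' Observation log-likelihood (measurement error)
#'
#' Log density of observed annual growth around the latent true growth
#' under the two-component mixture, with both standard deviations scaled
#' by the interval length `int` (an error of fixed size in the dbh
#' difference shrinks on the per-year scale as the interval grows).
#'
#' @param obs observed annual growth in mm/yr (may be negative).
#' @param true latent true annual growth in mm/yr.
#' @param dbh initial diameter in mm.
#' @param int interval length in years (> 0).
#' @param em an [error_model()].
#' @return Log densities.
#' @export
obs_loglik <- function(obs, true, dbh, int, em = error_model()) {
  stopifnot(all(int > 0))
  sd1 <- (em$s0 + em$s1 * dbh) / int
  sd2 <- em$sd2 / int
  e <- obs - true
  l1 <- log1p(-em$f) + dnorm(e, 0, sd1, log = TRUE)
  if (em$f == 0) return(l1)
  l2 <- log(em$f) + dnorm(e, 0, sd2, log = TRUE)
  m <- pmax(l1, l2)
  m + log(exp(l1 - m) + exp(l2 - m))
}

#' Process log-likelihood (biological variability)
#'
#' Lognormal density of the latent true growth around the predicted
#' growth: log-median `log(pred)`, log-sd `d`. The spread therefore
#' scales automatically with the predicted growth, and the median of the
#' implied distribution equals the prediction. Non-positive `true`
#' returns `-Inf`.
#'
#' @param true latent true growth in mm/yr.
#' @param pred predicted growth in mm/yr (> 0).
#' @param d process-error log-sd (> 0).
#' @return Log densities.
#' @export
process_loglik <- function(true, pred, d) {
  stopifnot(all(pred > 0), all(d > 0))
  n <- max(length(true), length(pred), length(d))
  true <- rep_len(true, n)
  pred <- rep_len(pred, n)
  d <- rep_len(d, n)
  out <- rep(-Inf, n)
  ok <- true > 0
  if (any(ok))
    out[ok] <- dlnorm(true[ok], log(pred[ok]), d[ok], log = TRUE)
  out
}

#' Quadrature marginal observation likelihood
#'
#' Numerically integrates the latent true growth out of the product of
#' process and observation densities. This is a diagnostic oracle (used
#' to validate the latent-variable sampler), not part of the fitting
#' path.
#'
#' @param obs observed annual growth in mm/yr (scalar).
#' @param pred predicted growth in mm/yr.
#' @param d process-error log-sd.
#' @inheritParams obs_loglik
#' @return Scalar log marginal density of `obs`.
#' @export
marginal_obs_loglik <- function(obs, pred, d, dbh, int, em = error_model()) {
  f <- function(t)
    exp(process_loglik(t, pred, d) + obs_loglik(obs, t, dbh, int, em))
  upper <- exp(log(pred) + 8 * d)
  val <- integrate(f, 0, upper, rel.tol = 1e-9,
                   subdivisions = 500L)$value
  log(val)
}

#' Growth-model hyperparameters
#'
#' Community regressions on log abundance for the intrinsic growth rate
#' `a`, the light response `b` and the size exponent `c`, plus a
#' community lognormal law for the process error `d` (parameters
#' `delta1`, `delta2` on the log scale). Regression defaults are
#' representative posterior values for a lowland tropical forest
#' (canopy-index model); the process-error law defaults (median ~0.7,
#' log-sd 0.3) are a package choice since community values are
#' site-specific.
#'
#' @param alpha1,alpha2,sigma_alpha regression for `a`.
#' @param beta1,beta2,sigma_beta regression for `b`.
#' @param gamma1,gamma2,sigma_gamma regression for `c`.
#' @param delta1,delta2 lognormal law for `d`.
#' @return Named numeric vector of class `growth_hypers`.
#' @export
growth_hypers <- function(alpha1 = -0.06, alpha2 = -0.06,
                          sigma_alpha = 0.48, beta1 = 0.86,
                          beta2 = -0.07, sigma_beta = 0.16,
                          gamma1 = -0.21, gamma2 = 0.04,
                          sigma_gamma = 0.26, delta1 = log(0.7),
                          delta2 = 0.3) {
  stopifnot(sigma_alpha > 0, sigma_beta > 0, sigma_gamma > 0, delta2 > 0)
  structure(c(alpha_g1 = alpha1, alpha_g2 = alpha2,
              sigma_g_alpha = sigma_alpha, beta_g1 = beta1,
              beta_g2 = beta2, sigma_g_beta = sigma_beta,
              gamma_1 = gamma1, gamma_2 = gamma2,
              sigma_gamma = sigma_gamma, delta_1 = delta1,
              delta_2 = delta2),
            class = "growth_hypers")
}

#' Growth-model log posterior
#'
#' Sum of the observation likelihood (measurement-error mixture), the
#' process likelihood of the latent true growth, the Normal community
#' regressions of `a`, `b`, `c` on log abundance, the lognormal law for
#' `d`, and flat hyperpriors. Returns `-Inf` outside the supports
#' (non-positive `d`, latent growth or scale hyperparameters).
#'
#' @param params list with vectors `a`, `b`, `c`, `d` (per species).
#' @param hypers a [growth_hypers()] (or named vector, same order).
#' @param latents latent true growth per record (mm/yr).
#' @param records `growth_records` (or data.frame with `species_id`,
#'   `dbh0`, `obs_growth`, `int`).
#' @param lnab log abundance per species (aligned with `params`).
#' @param em an [error_model()].
#' @param x centered log light per record.
#' @return Scalar log posterior.
#' @export
growth_log_posterior <- function(params, hypers, latents, records, lnab,
                                 em, x) {
  h <- as.numeric(hypers)[1:11]
  if (h[3] <= 0 || h[6] <= 0 || h[9] <= 0 || h[11] <= 0) return(-Inf)
  if (any(params$d <= 0)) return(-Inf)
  if (any(latents <= 0)) return(-Inf)
  sp <- match(records$species_id, sort(unique(records$species_id)))
  pred <- predict_growth(params$a[sp], params$b[sp], params$c[sp], x,
                         records$dbh0)
  sum(obs_loglik(records$obs_growth, latents, records$dbh0, records$int,
                 em)) +
    sum(process_loglik(latents, pred, params$d[sp])) +
    sum(dnorm(params$a, h[1] + h[2] * lnab, h[3], log = TRUE)) +
    sum(dnorm(params$b, h[4] + h[5] * lnab, h[6], log = TRUE)) +
    sum(dnorm(params$c, h[7] + h[8] * lnab, h[9], log = TRUE)) +
    sum(dlnorm(params$d, h[10], h[11], log = TRUE))
}

#' Fit the hierarchical growth model
#'
#' Metropolis-Hastings over species parameters, hyperparameters and the
#' latent true growth of every tree, organized in sweeps: within a sweep
#' each species-parameter family (`a`, `b`, `c`, `d`) is updated with
#' per-species Gaussian proposals (species are conditionally independent
#' given the hyperparameters, so element-wise accept/reject matches a
#' one-at-a-time scan), every latent true growth receives an individual
#' proposal (latents are conditionally independent given the species
#' parameters), and the eleven hyperparameters are updated one at a
#' time. Step sizes adapt toward 0.25 acceptance during burn-in and are
#' then frozen. Latents are initialized at `max(obs, 0.05)` mm/yr.
#' Summaries cover species parameters and hyperparameters; latents are
#' returned as posterior means only.
#'
#' @param records a `growth_records` data.frame (see
#'   [extract_growth_records()]), one row per tree.
#' @param light a [light_field()] at trees (aligned with `records` by
#'   `tree_id`), or numeric light values per record.
#' @param abundance named species abundance vector.
#' @param em an [error_model()].
#' @param n_chains number of chains.
#' @param n_burn,n_sample burn-in and sampling sweeps (defaults are
#'   desk-scale; convergence should be checked with [gelman_rubin()] on
#'   two chains or by inspection).
#' @param window,target step-tuning window (sweeps) and target
#'   acceptance.
#' @return A `treelight_fit` (see [fit_recruitment()]) with additional
#'   element `$latent_mean`.
#' @export
fit_growth <- function(records, light, abundance, em = error_model(),
                       n_chains = 1, n_burn = 2000, n_sample = 2000,
                       window = 50, target = 0.25) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (inherits(light, "light_field")) {
    light_scale <- if (attr(light, "scale") == "nci") "nci" else "log_cai"
    lv <- model_scale_light(light)
    m <- match(records$tree_id, light$id)
    if (anyNA(m)) stop("light field does not cover all growth records")
    lv <- lv[m]
  } else {
    light_scale <- "log_cai"
    stopifnot(length(light) == nrow(records))
    lv <- light
  }
  center <- mean(lv)
  x <- lv - center
  species <- sort(unique(records$species_id))
  if (is.null(names(abundance)) || !all(species %in% names(abundance)))
    stop("abundance must be named and cover all modeled species")
  lnab <- log(as.numeric(abundance[species]))
  S <- length(species)
  n <- nrow(records)
  sp <- match(records$species_id, species)
  z <- log(records$dbh0 / 50)
  obs <- records$obs_growth
  sd1 <- (em$s0 + em$s1 * records$dbh0) / records$int
  sd2 <- em$sd2 / records$int
  lf <- em$f
  obs_ll <- function(true) {
    e <- obs - true
    l1 <- log1p(-lf) + dnorm(e, 0, sd1, log = TRUE)
    if (lf == 0) return(l1)
    l2 <- log(lf) + dnorm(e, 0, sd2, log = TRUE)
    m0 <- pmax(l1, l2)
    m0 + log(exp(l1 - m0) + exp(l2 - m0))
  }
  par_names <- c(paste0("a[", species, "]"), paste0("b[", species, "]"),
                 paste0("c[", species, "]"), paste0("d[", species, "]"),
                 names(growth_hypers()))
  np <- 4 * S + 11
  a_lim <- c(-20, 10); b_lim <- c(-20, 20); c_lim <- c(-20, 20)
  d_lim <- c(1e-3, 10)
  hyp_lo <- c(-50, -20, 1e-3, -50, -20, 1e-3, -50, -20, 1e-3, -10, 1e-3)
  hyp_hi <- c(50, 20, 10, 50, 20, 10, 50, 20, 10, 5, 5)

  run_one <- function(chain_id) {
    med_obs <- tapply(pmax(obs, 0.05), sp, median)
    a <- pmin(pmax(log(as.numeric(med_obs)), a_lim[1] + 1), a_lim[2] - 1)
    if (chain_id == 1) {
      b <- rep(0.5, S); cc <- rep(0, S); d <- rep(0.5, S)
      hyp <- c(mean(a), 0, 0.5, 0.5, 0, 0.3, 0, 0, 0.3, log(0.5), 0.5)
    } else {
      b <- rep(1, S); cc <- rep(-0.2, S); d <- rep(1, S)
      hyp <- c(mean(a), -0.2, 1, 1, 0, 0.5, -0.3, 0, 0.5, log(1), 0.3)
    }
    true <- pmax(obs, 0.05)
    meanlog <- a[sp] + b[sp] * x + cc[sp] * z
    proc <- dlnorm(true, meanlog, d[sp], log = TRUE)
    obsl <- obs_ll(true)
    steps <- rep(0.2, np)
    lat_steps <- pmax(sd1, 0.05)
    acc_win <- numeric(np); lat_acc_win <- numeric(n); n_win <- 0L
    acc_tot <- numeric(np); lat_acc_tot <- 0
    lat_sum <- numeric(n)
    draws <- matrix(NA_real_, n_sample, np,
                    dimnames = list(NULL, par_names))
    hyp_ll <- function(hh)
      sum(dnorm(a, hh[1] + hh[2] * lnab, hh[3], log = TRUE)) +
      sum(dnorm(b, hh[4] + hh[5] * lnab, hh[6], log = TRUE)) +
      sum(dnorm(cc, hh[7] + hh[8] * lnab, hh[9], log = TRUE)) +
      sum(dlnorm(d, hh[10], hh[11], log = TRUE))
    for (it in seq_len(n_burn + n_sample)) {
      sampling <- it > n_burn
      # --- species families a, b, c (mean-log shifts) ---
      for (fam in 1:3) {
        idx <- (fam - 1) * S + 1:S
        cur <- switch(fam, a, b, cc)
        lim <- switch(fam, a_lim, b_lim, c_lim)
        mu_h <- hyp[(fam - 1) * 3 + 1] + hyp[(fam - 1) * 3 + 2] * lnab
        sd_h <- hyp[(fam - 1) * 3 + 3]
        prop <- cur + rnorm(S) * steps[idx]
        valid <- prop >= lim[1] & prop <= lim[2]
        delta <- (prop - cur)[sp] *
          switch(fam, rep(1, n), x, z)
        proc_new <- dlnorm(true, meanlog + delta, d[sp], log = TRUE)
        dll <- rowsum(proc_new - proc, sp, reorder = TRUE)[, 1]
        lr <- dll + dnorm(prop, mu_h, sd_h, log = TRUE) -
          dnorm(cur, mu_h, sd_h, log = TRUE)
        acc <- .accept_vec(lr, valid)
        if (any(acc)) {
          cur[acc] <- prop[acc]
          upd <- acc[sp]
          meanlog[upd] <- meanlog[upd] + delta[upd]
          proc[upd] <- proc_new[upd]
        }
        if (fam == 1) a <- cur else if (fam == 2) b <- cur else cc <- cur
        acc_win[idx] <- acc_win[idx] + acc
        if (sampling) acc_tot[idx] <- acc_tot[idx] + acc
      }
      # --- d family (process log-sd, lognormal community law) ---
      idx <- 3 * S + 1:S
      prop <- d + rnorm(S) * steps[idx]
      valid <- prop >= d_lim[1] & prop <= d_lim[2]
      prop_safe <- ifelse(valid, prop, d)
      proc_new <- dlnorm(true, meanlog, prop_safe[sp], log = TRUE)
      dll <- rowsum(proc_new - proc, sp, reorder = TRUE)[, 1]
      lr <- dll + ifelse(valid,
                         dlnorm(prop_safe, hyp[10], hyp[11], log = TRUE) -
                           dlnorm(d, hyp[10], hyp[11], log = TRUE), -Inf)
      acc <- .accept_vec(lr, valid)
      if (any(acc)) {
        d[acc] <- prop[acc]
        upd <- acc[sp]
        proc[upd] <- proc_new[upd]
      }
      acc_win[idx] <- acc_win[idx] + acc
      if (sampling) acc_tot[idx] <- acc_tot[idx] + acc
      # --- latent true growth (element-wise) ---
      tprop <- true + rnorm(n) * lat_steps
      tvalid <- tprop > 0
      tsafe <- ifelse(tvalid, tprop, true)
      proc_new <- dlnorm(tsafe, meanlog, d[sp], log = TRUE)
      obs_new <- obs_ll(tsafe)
      lr <- proc_new + obs_new - proc - obsl
      acc <- .accept_vec(lr, tvalid)
      if (any(acc)) {
        true[acc] <- tprop[acc]
        proc[acc] <- proc_new[acc]
        obsl[acc] <- obs_new[acc]
      }
      lat_acc_win <- lat_acc_win + acc
      if (sampling) {
        lat_acc_tot <- lat_acc_tot + mean(acc)
        lat_sum <- lat_sum + true
      }
      # --- hyperparameters ---
      cur_hll <- hyp_ll(hyp)
      for (j in 1:11) {
        idx <- 4 * S + j
        hp <- hyp
        hp[j] <- hyp[j] + rnorm(1) * steps[idx]
        if (hp[j] < hyp_lo[j] || hp[j] > hyp_hi[j]) next
        new_hll <- hyp_ll(hp)
        if (log(runif(1)) < new_hll - cur_hll) {
          hyp <- hp; cur_hll <- new_hll
          acc_win[idx] <- acc_win[idx] + 1
          if (sampling) acc_tot[idx] <- acc_tot[idx] + 1
        }
      }
      n_win <- n_win + 1L
      if (!sampling && n_win == window) {
        rate <- acc_win / n_win
        steps <- tune_steps(steps, rate, target = target,
                            factor = exp(2 * abs(rate - target)))
        lrate <- lat_acc_win / n_win
        lat_steps <- tune_steps(lat_steps, lrate, target = target,
                                factor = exp(2 * abs(lrate - target)))
        acc_win[] <- 0; lat_acc_win[] <- 0; n_win <- 0L
      }
      if (sampling) draws[it - n_burn, ] <- c(a, b, cc, d, hyp)
    }
    structure(list(draws = draws, acceptance = acc_tot / n_sample,
                   latent_acceptance = lat_acc_tot / n_sample,
                   latent_mean = lat_sum / n_sample, steps = steps,
                   n_burn = n_burn),
              class = "mcmc_chain")
  }

  chains <- lapply(seq_len(n_chains), run_one)
  traces <- lapply(chains, `[[`, "draws")
  rhat <- if (n_chains >= 2) gelman_rubin(traces) else NULL
  acceptance <- rowMeans(sapply(chains, `[[`, "acceptance"))
  names(acceptance) <- par_names
  structure(list(model = "growth", traces = traces,
                 summary = summarize_trace(traces), rhat = rhat,
                 acceptance = acceptance,
                 latent_mean = rowMeans(sapply(chains, `[[`, "latent_mean")),
                 species = species, center = center,
                 light_scale = light_scale, n_burn = n_burn,
                 n_sample = n_sample),
            class = "treelight_fit")
}
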