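# Hierarchical Bayesian model of per-cell recruit counts: a power
# function of light (linear on the log-log scale) with negative-binomial
# overdispersion per species and abundance-dependent community-level
# regressions on the species parameters.

#' Predicted recruit count
#'
#' `exp(a + b * x)` with `x` the centered log light: a power function of
#' light. `a` is the log recruit count per cell at mean light and `b` the
#' light-response exponent (`b < 0` negative, `0 < b < 1` decelerating,
#' `b = 1` linear, `b > 1` accelerating response).
#'
#' @param a,b species parameters.
#' @param x centered log light.
#' @return Predicted mean counts (> 0).
#' @export
predict_recruits <- function(a, b, x) exp(a + b * x)

#' Negative-binomial log-likelihood
#'
#' Mean-clumping parameterization: mean `mu` and variance
#' `mu + mu^2 / k`; small `k` means strong spatial clumping, and for
#' `k > 10` the distribution already approximates a homogeneous Poisson.
#'
#' @param obs non-negative integer counts.
#' @param mu positive means.
#' @param k positive clumping parameters.
#' @return Log-probabilities.
#' @export
nb_loglik <- function(obs, mu, k) {
  if (any(obs < 0) || any(obs != round(obs)))
    stop("obs must be non-negative integers")
  if (any(mu <= 0) || any(k <= 0)) stop("mu and k must be positive")
  dnbinom(obs, size = k, mu = mu, log = TRUE)
}

#' Recruitment-model hyperparameters
#'
#' Community-level regressions of the species parameters on log
#' abundance: `a_j ~ Normal(alpha1 + alpha2 * ln(abun_j), sigma_alpha)`
#' and `b_j ~ Normal(beta1 + beta2 * ln(abun_j), sigma_beta)`. Defaults
#' are representative posterior values for a lowland tropical forest
#' community (canopy-index model): common species recruit more per cell
#' but respond less strongly to light.
#'
#' @param alpha1,alpha2,sigma_alpha intercept regression (on `a`).
#' @param beta1,beta2,sigma_beta light-response regression (on `b`).
#' @return Named numeric vector of class `recruit_hypers`.
#' @export
recruit_hypers <- function(alpha1 = -10.59, alpha2 = 0.78,
                           sigma_alpha = 0.97, beta1 = 1.60,
                           beta2 = -0.15, sigma_beta = 0.67) {
  stopifnot(sigma_alpha > 0, sigma_beta > 0)
  structure(c(alpha_r1 = alpha1, alpha_r2 = alpha2,
              sigma_r_alpha = sigma_alpha, beta_r1 = beta1,
              beta_r2 = beta2, sigma_r_beta = sigma_beta),
            class = "recruit_hypers")
}

# per-species NB log-likelihood over all cells; Y is cells x species
.recruit_ll_species <- function(Y, x, a, b, k) {
  ncell <- nrow(Y)
  mu <- exp(outer(x, b) + rep(a, each = ncell))
  ll <- dnbinom(Y, size = rep(k, each = ncell), mu = mu, log = TRUE)
  dim(ll) <- dim(Y)
  colSums(ll)
}

#' Recruitment-model log posterior
#'
#' Sum of the negative-binomial likelihood over cells and species, the
#' Normal community regressions of `a` and `b` on log abundance, and the
#' flat priors: `k` uniform on (0, 100], standard deviations positive,
#' everything else unbounded. Returns `-Inf` (never raises) outside the
#' supports.
#'
#' @param a,b,k species parameter vectors.
#' @param hypers a [recruit_hypers()] (or named vector with the same
#'   elements).
#' @param Y counts matrix, cells x species.
#' @param lnab log abundance per species.
#' @param x centered log light per cell.
#' @return Scalar log posterior.
#' @export
recruit_log_posterior <- function(a, b, k, hypers, Y, lnab, x) {
  h <- as.numeric(hypers)[1:6]
  names(h) <- c("alpha_r1", "alpha_r2", "sigma_r_alpha",
                "beta_r1", "beta_r2", "sigma_r_beta")
  if (h["sigma_r_alpha"] <= 0 || h["sigma_r_beta"] <= 0) return(-Inf)
  if (any(k <= 0 | k > 100)) return(-Inf)
  ll <- sum(.recruit_ll_species(Y, x, a, b, k))
  prior <- sum(dnorm(a, h["alpha_r1"] + h["alpha_r2"] * lnab,
                     h["sigma_r_alpha"], log = TRUE)) +
    sum(dnorm(b, h["beta_r1"] + h["beta_r2"] * lnab,
              h["sigma_r_beta"], log = TRUE))
  ll + prior
}

# elementwise MH accept for a vectorized family update; returns logical
.accept_vec <- function(log_ratio, valid) {
  acc <- valid & log(runif(length(log_ratio))) < log_ratio
  acc & !is.na(acc)
}

#' Fit the hierarchical recruitment model
#'
#' Adaptive Metropolis-Hastings within a Gibbs-style full scan: every
#' iteration updates each species' `a`, `b` and `k` and then the six
#' hyperparameters, each with its own Gaussian random-walk proposal.
#' Step sizes are tuned multiplicatively toward 0.25 acceptance during
#' burn-in and frozen for the sampling phase. Species parameters are
#' proposed jointly across species within a family (species are
#' conditionally independent given the hyperparameters, so the
#' element-wise accept/reject is equivalent to a sequential scan) which
#' keeps the likelihood evaluation vectorized. Light is centered
#' internally; the centering constant is stored with the fit.
#'
#' @param recruits a `recruit_table` (or counts matrix cells x species).
#' @param light a [light_field()] at cells, or numeric light values per
#'   cell; canopy-index values are log-transformed, NCI-scale values are
#'   used as-is.
#' @param abundance named vector of species abundance at interval start.
#' @param n_chains number of chains (different initial values).
#' @param n_burn,n_sample burn-in and sampling iterations.
#' @param window,target step-tuning window and target acceptance.
#' @return An object of class `treelight_fit`: `$traces` (per chain),
#'   `$summary` (posterior mean and 95% CI per parameter), `$rhat`,
#'   `$acceptance`, `$species`, `$center`, `$light_scale`.
#' @export
fit_recruitment <- function(recruits, light, abundance, n_chains = 2,
                            n_burn = 1000, n_sample = 6000, window = 50,
                            target = 0.25) {
  Y <- if (inherits(recruits, "recruit_table")) as.matrix(recruits)
       else as.matrix(recruits)
  if (!nrow(Y) || !ncol(Y)) stop("no recruit data to fit")
  species <- colnames(Y)
  if (any(colSums(Y) == 0))
    stop("every modeled species needs at least one recruit")
  light_scale <- "log_cai"
  if (inherits(light, "light_field")) {
    light_scale <- if (attr(light, "scale") == "nci") "nci" else "log_cai"
    stopifnot(nrow(light) == nrow(Y))
    lv <- model_scale_light(light)
  } else {
    stopifnot(length(light) == nrow(Y))
    lv <- light
  }
  center <- mean(lv)
  x <- lv - center
  if (is.null(names(abundance)) || !all(species %in% names(abundance)))
    stop("abundance must be named and cover all modeled species")
  lnab <- log(as.numeric(abundance[species]))
  S <- length(species)
  par_names <- c(paste0("a[", species, "]"), paste0("b[", species, "]"),
                 paste0("k[", species, "]"),
                 names(recruit_hypers()))
  a_lim <- c(-30, 10); b_lim <- c(-20, 20); k_lim <- c(1e-3, 100)
  hyp_lo <- c(-50, -20, 1e-3, -50, -20, 1e-3)
  hyp_hi <- c(50, 20, 20, 50, 20, 20)

  run_one <- function(chain_id) {
    a <- pmin(pmax(log(colMeans(Y) + 0.01), a_lim[1] + 1), a_lim[2] - 1)
    if (chain_id == 1) {
      b <- rep(0, S); k <- rep(5, S)
      hyp <- c(mean(a), 0, 1, 0, 0, 1)
    } else {
      b <- rep(1, S); k <- rep(20, S)
      hyp <- c(mean(a), 0.5, 0.5, 1, 0, 0.5)
    }
    steps <- c(rep(0.2, 2 * S), rep(5, S), rep(0.2, 6))
    ll_sp <- .recruit_ll_species(Y, x, a, b, k)
    hyp_ll <- function(hh)
      sum(dnorm(a, hh[1] + hh[2] * lnab, hh[3], log = TRUE)) +
      sum(dnorm(b, hh[4] + hh[5] * lnab, hh[6], log = TRUE))
    acc_win <- numeric(3 * S + 6); n_win <- 0L
    acc_tot <- numeric(3 * S + 6)
    draws <- matrix(NA_real_, n_sample, 3 * S + 6,
                    dimnames = list(NULL, par_names))
    mu_a <- hyp[1] + hyp[2] * lnab
    mu_b <- hyp[4] + hyp[5] * lnab
    for (it in seq_len(n_burn + n_sample)) {
      sampling <- it > n_burn
      # --- a family ---
      idx <- 1:S
      prop <- a + rnorm(S) * steps[idx]
      valid <- prop >= a_lim[1] & prop <= a_lim[2]
      ll_new <- .recruit_ll_species(Y, x, prop, b, k)
      lr <- ll_new - ll_sp +
        dnorm(prop, mu_a, hyp[3], log = TRUE) -
        dnorm(a, mu_a, hyp[3], log = TRUE)
      acc <- .accept_vec(lr, valid)
      a[acc] <- prop[acc]; ll_sp[acc] <- ll_new[acc]
      acc_win[idx] <- acc_win[idx] + acc
      if (sampling) acc_tot[idx] <- acc_tot[idx] + acc
      # --- b family ---
      idx <- S + 1:S
      prop <- b + rnorm(S) * steps[idx]
      valid <- prop >= b_lim[1] & prop <= b_lim[2]
      ll_new <- .recruit_ll_species(Y, x, a, prop, k)
      lr <- ll_new - ll_sp +
        dnorm(prop, mu_b, hyp[6], log = TRUE) -
        dnorm(b, mu_b, hyp[6], log = TRUE)
      acc <- .accept_vec(lr, valid)
      b[acc] <- prop[acc]; ll_sp[acc] <- ll_new[acc]
      acc_win[idx] <- acc_win[idx] + acc
      if (sampling) acc_tot[idx] <- acc_tot[idx] + acc
      # --- k family (flat prior on (0, 100]) ---
      idx <- 2 * S + 1:S
      prop <- k + rnorm(S) * steps[idx]
      valid <- prop >= k_lim[1] & prop <= k_lim[2]
      prop_safe <- ifelse(valid, prop, k)
      ll_new <- .recruit_ll_species(Y, x, a, b, prop_safe)
      lr <- ll_new - ll_sp
      acc <- .accept_vec(lr, valid)
      k[acc] <- prop[acc]; ll_sp[acc] <- ll_new[acc]
      acc_win[idx] <- acc_win[idx] + acc
      if (sampling) acc_tot[idx] <- acc_tot[idx] + acc
      # --- hyperparameters (flat priors within bounds) ---
      cur_hll <- hyp_ll(hyp)
      for (j in 1:6) {
        idx <- 3 * S + j
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
      mu_a <- hyp[1] + hyp[2] * lnab
      mu_b <- hyp[4] + hyp[5] * lnab
      n_win <- n_win + 1L
      if (!sampling && n_win == window) {
        rate <- acc_win / n_win
        steps <- tune_steps(steps, rate, target = target,
                            factor = exp(2 * abs(rate - target)))
        acc_win[] <- 0; n_win <- 0L
      }
      if (sampling) draws[it - n_burn, ] <- c(a, b, k, hyp)
    }
    structure(list(draws = draws, acceptance = acc_tot / n_sample,
                   steps = steps, n_burn = n_burn),
              class = "mcmc_chain")
  }

  chains <- lapply(seq_len(n_chains), run_one)
  traces <- lapply(chains, `[[`, "draws")
  rhat <- if (n_chains >= 2) gelman_rubin(traces) else NULL
  acceptance <- rowMeans(sapply(chains, `[[`, "acceptance"))
  names(acceptance) <- par_names
  structure(list(model = "recruitment", traces = traces,
                 summary = summarize_trace(traces), rhat = rhat,
                 acceptance = acceptance, species = species,
                 center = center, light_scale = light_scale,
                 n_burn = n_burn, n_sample = n_sample),
            class = "treelight_fit")
}

#' @export
print.treelight_fit <- function(x, ...) {
  cat("<treelight_fit>", x$model, "model:", length(x$species), "species,",
      length(x$traces), "chain(s) x", x$n_sample, "draws\n")
  if (!is.null(x$rhat))
    cat("  max R-hat:", round(max(x$rhat), 3), "\n")
  invisible(x)
}

#' Extract a parameter family from a fit summary
#'
#' @param fit a `treelight_fit`.
#' @param family parameter prefix, e.g. `"b"` for the light response.
#' @return data.frame `species`, `mean`, `lo`, `hi`.
#' @export
species_params <- function(fit, family = "b") {
  stopifnot(inherits(fit, "treelight_fit"))
  s <- fit$summary
  pref <- paste0(family, "[")
  sel <- startsWith(s$parameter, pref)
  sp <- sub("\\]$", "", substring(s$parameter[sel], nchar(pref) + 1))
  data.frame(species = sp, mean = s$mean[sel], lo = s$lo[sel],
             hi = s$hi[sel], row.names = NULL, stringsAsFactors = FALSE)
}
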