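# Generic MCMC machinery: adaptive Metropolis-Hastings with Gaussian
# random-walk proposals, either as a full scan over all parameters per
# iteration (Metropolis-within-Gibbs) or as a single-site sampler that
# updates one parameter per iteration; plus step-size tuning toward a
# target acceptance rate, the Gelman-Rubin convergence diagnostic and
# posterior summaries.

#' Parameter specifications for MCMC
#'
#' @param name parameter names.
#' @param init initial values (within support).
#' @param lower,upper support bounds (may be infinite); proposals outside
#'   the support are rejected outright.
#' @param step initial Gaussian proposal standard deviations.
#' @return data.frame of class `param_spec`.
#' @export
param_spec <- function(name, init, lower = -Inf, upper = Inf, step = 0.1) {
  n <- length(name)
  out <- data.frame(name = name, init = init,
                    lower = rep_len(lower, n), upper = rep_len(upper, n),
                    step = rep_len(step, n), stringsAsFactors = FALSE)
  if (any(out$lower >= out$upper)) stop("lower must be < upper")
  if (any(out$init < out$lower | out$init > out$upper))
    stop("initial values outside support")
  class(out) <- c("param_spec", "data.frame")
  out
}

#' One Metropolis-Hastings scan over all parameters
#'
#' Updates each parameter in sequence with a Gaussian random-walk
#' proposal; a proposal outside the support is rejected outright,
#' otherwise it is accepted with the standard MH ratio on the
#' log-posterior.
#'
#' @param log_post function of the full parameter vector returning the
#'   log posterior (may be `-Inf` outside the support).
#' @param state current parameter vector.
#' @param specs a [param_spec()] (its `step` column is the proposal sd).
#' @param lp current log-posterior value (recomputed if missing).
#' @return list with `state`, `accepted` (logical per parameter) and
#'   `lp` (log posterior at the new state).
#' @export
mh_scan <- function(log_post, state, specs, lp = NULL) {
  if (is.null(lp)) lp <- log_post(state)
  if (is.nan(lp)) stop("log-posterior is NaN at the current state")
  accepted <- logical(length(state))
  for (i in seq_along(state)) {
    prop <- state
    prop[i] <- state[i] + rnorm(1, 0, specs$step[i])
    if (prop[i] < specs$lower[i] || prop[i] > specs$upper[i]) next
    lp_new <- log_post(prop)
    if (is.nan(lp_new)) stop("log-posterior is NaN at a proposal")
    if (log(runif(1)) < lp_new - lp) {
      state <- prop; lp <- lp_new; accepted[i] <- TRUE
    }
  }
  list(state = state, accepted = accepted, lp = lp)
}

#' Single-site Metropolis-Hastings update
#'
#' As [mh_scan()] but exactly one parameter (in cyclic order) is updated
#' per call.
#'
#' @inheritParams mh_scan
#' @param index which parameter to update.
#' @return list with `state`, `accepted` (scalar), `lp`.
#' @export
single_site_scan <- function(log_post, state, specs, index, lp = NULL) {
  if (is.null(lp)) lp <- log_post(state)
  if (is.nan(lp)) stop("log-posterior is NaN at the current state")
  accepted <- FALSE
  prop <- state
  prop[index] <- state[index] + rnorm(1, 0, specs$step[index])
  if (prop[index] >= specs$lower[index] && prop[index] <= specs$upper[index]) {
    lp_new <- log_post(prop)
    if (is.nan(lp_new)) stop("log-posterior is NaN at a proposal")
    if (log(runif(1)) < lp_new - lp) {
      state <- prop; lp <- lp_new; accepted <- TRUE
    }
  }
  list(state = state, accepted = accepted, lp = lp)
}

#' Multiplicative step-size tuning
#'
#' Adjusts proposal step sizes toward a target acceptance rate: a step is
#' multiplied by `factor` when its windowed acceptance exceeds the
#' target and divided by `factor` when it falls below. Intended for the
#' burn-in phase only; steps must be frozen afterwards so the sampling
#' phase is a valid fixed-kernel chain.
#'
#' @param steps current step sizes.
#' @param accept_rate acceptance rate(s) over the last window.
#' @param target target acceptance rate (default 0.25).
#' @param factor multiplicative adjustment (default 1.1); may be a
#'   vector. The model samplers pass `exp(2 * |rate - target|)` so that
#'   badly mis-scaled steps move quickly while steps near the target
#'   barely change.
#' @return Adjusted step sizes.
#' @export
tune_steps <- function(steps, accept_rate, target = 0.25, factor = 1.1) {
  stopifnot(all(steps > 0), all(factor >= 1))
  ifelse(accept_rate > target, steps * factor,
         ifelse(accept_rate < target, steps / factor, steps))
}

#' Run an adaptive Metropolis-Hastings chain
#'
#' Runs `n_burn` adaptation iterations (step sizes tuned every `window`
#' iterations toward the target acceptance rate) followed by `n_sample`
#' fixed-kernel sampling iterations. `scan = "full"` updates every
#' parameter each iteration (the recruitment-model scheme);
#' `scan = "single"` updates one parameter per iteration in cyclic order
#' (the growth-model scheme).
#'
#' @param log_post log-posterior function of the parameter vector.
#' @param specs a [param_spec()].
#' @param n_burn,n_sample burn-in and sampling iterations.
#' @param scan `"full"` or `"single"`.
#' @param window adaptation window in iterations (default 50).
#' @param target target acceptance rate (default 0.25).
#' @return list of class `mcmc_chain`: `draws` (n_sample x n_par matrix),
#'   `acceptance` (per-parameter realized rate over the sampling phase),
#'   `steps` (final step sizes), `n_burn`.
#' @export
run_chain <- function(log_post, specs, n_burn = 1000, n_sample = 6000,
                      scan = c("full", "single"), window = 50,
                      target = 0.25) {
  scan <- match.arg(scan)
  stopifnot(inherits(specs, "param_spec"), n_burn >= 0, n_sample > 0)
  state <- specs$init
  np <- length(state)
  lp <- log_post(state)
  if (is.nan(lp) || !is.finite(lp))
    stop("log-posterior not finite at the initial state")
  steps <- specs$step
  acc_win <- numeric(np); try_win <- numeric(np)
  site <- 0L
  for (it in seq_len(n_burn)) {
    sp <- specs; sp$step <- steps
    if (scan == "full") {
      res <- mh_scan(log_post, state, sp, lp)
      acc_win <- acc_win + res$accepted
      try_win <- try_win + 1
    } else {
      site <- site %% np + 1L
      res <- single_site_scan(log_post, state, sp, site, lp)
      acc_win[site] <- acc_win[site] + res$accepted
      try_win[site] <- try_win[site] + 1
    }
    state <- res$state; lp <- res$lp
    if (it %% window == 0) {
      tried <- try_win > 0
      rate <- acc_win[tried] / try_win[tried]
      steps[tried] <- tune_steps(steps[tried], rate, target = target,
                                 factor = exp(2 * abs(rate - target)))
      acc_win[] <- 0; try_win[] <- 0
    }
  }
  draws <- matrix(NA_real_, n_sample, np,
                  dimnames = list(NULL, specs$name))
  acc <- numeric(np); tries <- numeric(np)
  sp <- specs; sp$step <- steps
  for (it in seq_len(n_sample)) {
    if (scan == "full") {
      res <- mh_scan(log_post, state, sp, lp)
      acc <- acc + res$accepted
      tries <- tries + 1
    } else {
      site <- site %% np + 1L
      res <- single_site_scan(log_post, state, sp, site, lp)
      acc[site] <- acc[site] + res$accepted
      tries[site] <- tries[site] + 1
    }
    state <- res$state; lp <- res$lp
    draws[it, ] <- state
  }
  structure(list(draws = draws, acceptance = acc / pmax(tries, 1),
                 steps = steps, n_burn = n_burn),
            class = "mcmc_chain")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes `sqrt(((n - 1) / n * W + B / n) / W)` per parameter, with `W`
#' the mean within-chain variance and `B` the between-chain variance of
#' the chain means (times n). Values are floored at 1; values below 1.1
#' conventionally indicate convergence.
#'
#' @param traces list of >= 2 draw matrices (iterations x parameters,
#'   burn-in already removed) with equal dimensions.
#' @return Named vector of R-hat values.
#' @export
gelman_rubin <- function(traces) {
  if (!is.list(traces) || length(traces) < 2)
    stop("gelman_rubin needs at least 2 chains")
  dims <- lapply(traces, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("chains must have equal dimensions")
  n <- nrow(traces[[1]])
  means <- sapply(traces, colMeans)                  # np x m
  vars <- sapply(traces, function(tr) apply(tr, 2, var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W == 0 & B == 0] <- 1
  setNames(pmax(rhat, 1), colnames(traces[[1]]))
}

#' Posterior summaries of a trace
#'
#' Mean and central 95% credible interval (2.5% and 97.5% empirical
#' quantiles, linear interpolation of order statistics) per parameter.
#'
#' @param trace a draw matrix (iterations x parameters), an `mcmc_chain`,
#'   or a list of either (chains are concatenated).
#' @return data.frame with `parameter`, `mean`, `lo`, `hi`.
#' @export
summarize_trace <- function(trace) {
  if (inherits(trace, "mcmc_chain")) trace <- trace$draws
  if (is.list(trace))
    trace <- do.call(rbind, lapply(trace, function(tr)
      if (inherits(tr, "mcmc_chain")) tr$draws else tr))
  stopifnot(is.matrix(trace), nrow(trace) > 0)
  qs <- apply(trace, 2, quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  data.frame(parameter = colnames(trace), mean = colMeans(trace),
             lo = qs[1, ], hi = qs[2, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export a trace as delimited text
#'
#' One column per parameter with '#'-prefixed metadata lines (chain id,
#' burn-in) ahead of the header.
#'
#' @param chain an `mcmc_chain`.
#' @param path output file.
#' @param chain_id chain identifier recorded in the metadata.
#' @export
write_trace <- function(chain, path, chain_id = 1) {
  stopifnot(inherits(chain, "mcmc_chain"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# chain", chain_id),
               paste("# burn_in", chain$n_burn)), con)
  write.table(chain$draws, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
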