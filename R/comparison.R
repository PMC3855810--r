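# Light-response classification, cross-model agreement and the
# end-to-end synthetic pipeline.

#' Classify a species' light response
#'
#' Mean-based class: negative (`mean < 0`), accelerating (`mean > 1`),
#' otherwise decelerating (boundary values 0 and 1 are assigned to
#' decelerating, a measure-zero convention). CI-based class: the class
#' whose open region contains the entire 95% CI, else `"unclassified"`.
#' The interpretation only holds for light on the log canopy-index
#' scale, not for raw competition indices.
#'
#' @param mean posterior mean of the light-response exponent.
#' @param lo,hi 95% CI bounds (`lo <= mean <= hi`).
#' @return data.frame with `class_mean` and `class_ci` (vectorized).
#' @examples
#' classify_light_response(1.2, 0.8, 1.6)  # accelerating / unclassified
#' @export
classify_light_response <- function(mean, lo, hi) {
  if (any(lo > hi)) stop("CI lower bound exceeds upper bound")
  if (any(mean < lo | mean > hi)) stop("mean outside its CI")
  cl_mean <- ifelse(mean < 0, "negative",
                    ifelse(mean > 1, "accelerating", "decelerating"))
  cl_ci <- ifelse(hi < 0, "negative",
                  ifelse(lo > 0 & hi < 1, "decelerating",
                         ifelse(lo > 1, "accelerating", "unclassified")))
  data.frame(class_mean = cl_mean, class_ci = cl_ci,
             stringsAsFactors = FALSE)
}

#' Classify every species of a fit
#'
#' Applies [classify_light_response()] to the posterior summaries of the
#' light-response exponents (`b`) of a fitted model. Refused for fits on
#' the raw NCI scale: the decelerating/accelerating interpretation of
#' the exponent requires light on the log canopy-index scale.
#'
#' @param fit a `treelight_fit`.
#' @return data.frame with `species`, `mean`, `lo`, `hi`, `class_mean`,
#'   `class_ci`.
#' @export
classify_species <- function(fit) {
  stopifnot(inherits(fit, "treelight_fit"))
  if (fit$light_scale == "nci")
    stop("light-response classes are not interpretable for fits on the ",
         "raw (untransformed) neighborhood competition index; refit on ",
         "the log canopy-index scale or with a converted NCI")
  b <- species_params(fit, "b")
  cbind(b, classify_light_response(b$mean, b$lo, b$hi))
}

#' Consistency of classifications across runs
#'
#' A species counts toward a class iff it received that class in every
#' compared run (e.g. both census intervals, or two light-estimation
#' approaches); otherwise it counts as inconsistent. Computed separately
#' for the mean-based and the CI-based classifications (for the CI-based
#' version, species unclassified everywhere are reported as
#' `unclassified`).
#'
#' @param classifications list of [classify_species()] results sharing
#'   species.
#' @return list with `species` (per-species consensus classes) and
#'   `counts` (class tallies per criterion).
#' @export
consistency_table <- function(classifications) {
  stopifnot(is.list(classifications), length(classifications) >= 2)
  shared <- Reduce(intersect, lapply(classifications, `[[`, "species"))
  if (!length(shared)) stop("no overlapping species across runs")
  per <- lapply(classifications, function(cl)
    cl[match(shared, cl$species), ])
  consensus <- function(col) {
    m <- sapply(per, `[[`, col)
    if (is.null(dim(m))) m <- rbind(m)
    apply(m, 1, function(v) if (length(unique(v)) == 1) v[1] else "inconsistent")
  }
  sp <- data.frame(species = shared,
                   class_mean = consensus("class_mean"),
                   class_ci = consensus("class_ci"),
                   stringsAsFactors = FALSE)
  lv <- c("negative", "decelerating", "accelerating", "unclassified",
          "inconsistent")
  counts <- rbind(
    mean = table(factor(sp$class_mean, levels = lv)),
    ci = table(factor(sp$class_ci, levels = lv)))
  list(species = sp, counts = counts)
}

#' Agreement of light-response estimates between two fits
#'
#' Pearson correlation of the posterior means across shared species,
#' the mean signed deviation from the 1:1 line (`model2 - model1`) and
#' the major-axis slope (the symmetric line through the scatter).
#'
#' @param fit1,fit2 `treelight_fit` objects (or data.frames from
#'   [species_params()]).
#' @param family parameter family to compare (default `"b"`).
#' @return list with `r`, `mean_deviation`, `ma_slope`, `n`.
#' @export
cross_model_agreement <- function(fit1, fit2, family = "b") {
  get_b <- function(f)
    if (inherits(f, "treelight_fit")) species_params(f, family) else f
  b1 <- get_b(fit1); b2 <- get_b(fit2)
  shared <- intersect(b1$species, b2$species)
  if (length(shared) < 3) stop("fewer than 3 shared species")
  v1 <- b1$mean[match(shared, b1$species)]
  v2 <- b2$mean[match(shared, b2$species)]
  sxx <- var(v1); syy <- var(v2); sxy <- cov(v1, v2)
  ma <- if (sxy == 0) NA_real_ else
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  list(r = cor(v1, v2), mean_deviation = mean(v2 - v1), ma_slope = ma,
       n = length(shared))
}

#' Default pipeline configuration
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param n_intervals number of synthetic census intervals (1 or 2).
#' @param stand a [stand_config()] (its seed is overridden per interval).
#' @param margin,cell_size core gridding (margin scaled to the plot).
#' @param mcmc list with `n_chains`, `n_burn`, `n_sample` for the
#'   recruitment fits.
#' @param light_estimates subset of `"log_cai"`, `"nci_ts"`, `"nci_tg"`,
#'   `"nci_raw"` to fit.
#' @param classify produce classification tables (refused for
#'   `"nci_raw"`).
#' @param alphas,betas grid-search exponent grids.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_intervals = 2,
                            stand = stand_config(plot_width = 120,
                                                 plot_height = 120,
                                                 richness = 30),
                            margin = 30, cell_size = 5,
                            mcmc = list(n_chains = 2, n_burn = 200,
                                        n_sample = 600),
                            light_estimates = c("log_cai", "nci_ts",
                                                "nci_tg"),
                            classify = TRUE,
                            alphas = seq(0, 3, by = 0.2),
                            betas = seq(0, 3, by = 0.2)) {
  cfg <- list(seed = as.integer(seed), n_intervals = n_intervals,
              stand = stand, margin = margin, cell_size = cell_size,
              mcmc = mcmc, light_estimates = light_estimates,
              classify = classify, alphas = alphas, betas = betas)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.known_estimates <- c("log_cai", "nci_ts", "nci_tg", "nci_raw")

#' Run the synthetic comparison pipeline
#'
#' End-to-end workflow on synthetic stands: generate one stand per
#' census interval, compute the canopy index for its core grid cells,
#' run the NCI grid search against log(CAI) across intervals, fit the
#' interval-specific and general (pooled) zero-intercept median
#' regressions, simulate recruit counts from ground-truth parameters
#' drawn from the community hyper-model, fit the recruitment model per
#' interval and light estimate, and produce classification and
#' agreement tables. Fully reproducible under the master seed. All
#' validation of the configuration happens before any computation.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, summary tables, the
#'   grid-search surface and the resolved configuration are written
#'   there as delimited text/JSON.
#' @return list with `grid_search`, `conversions`, `fits` (per interval
#'   and estimate), `classifications`, `consistency`, `agreement`,
#'   `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("seed", "n_intervals", "stand", "margin", "cell_size",
             "mcmc", "light_estimates", "classify", "alphas", "betas")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown pipeline config keys: ", paste(extra, collapse = ", "))
  bad <- setdiff(config$light_estimates, .known_estimates)
  if (length(bad))
    stop("unknown light estimates: ", paste(bad, collapse = ", "))
  if (config$classify && "nci_raw" %in% config$light_estimates)
    stop("classification of light responses is not available for the raw ",
         "(untransformed) neighborhood competition index: its exponent ",
         "has no decelerating/accelerating interpretation. Drop 'nci_raw' ",
         "or set classify = FALSE.")
  if (!config$n_intervals %in% 1:2)
    stop("n_intervals must be 1 or 2")
  allom <- allometry_config(height_cap = config$stand$canopy_height)
  grid <- partition_core(config$stand$plot_width, config$stand$plot_height,
                         config$margin, config$cell_size)

  intervals <- lapply(seq_len(config$n_intervals), function(i) {
    sc <- config$stand
    sc$seed <- config$seed * 1000L + i
    snap <- generate_stand(sc, census_year = 1985 + 5 * (i - 1))
    canopy <- generate_canopy_census(snap, allom, config$cell_size)
    cai <- cai_for_cells(list(canopy), grid)
    prof <- nci_profiles_for_cells(grid, snap, nci_config(1, 1),
                                   allom)
    list(snapshot = snap, cai = cai, profile = prof,
         log_cai = log(cai$value))
  })

  gs <- nci_grid_search(lapply(intervals, function(iv)
    list(profile = iv$profile, log_light = iv$log_cai)),
    alphas = config$alphas, betas = config$betas)

  nci_vals <- lapply(intervals, function(iv)
    nci_evaluate(iv$profile, gs$alpha, gs$beta))
  conv_ts <- lapply(seq_along(intervals), function(i)
    fit_conversion(nci_vals[[i]], intervals[[i]]$log_cai, degree = 1))
  conv_tg <- fit_conversion(unlist(nci_vals),
                            unlist(lapply(intervals, `[[`, "log_cai")),
                            degree = 1)

  hyp <- recruit_hypers()
  fits <- list(); classifications <- list()
  truth_by_interval <- list()
  for (i in seq_along(intervals)) {
    iv <- intervals[[i]]
    abun <- compute_abundance(iv$snapshot)
    truth <- draw_species_params(hyp, abun, seed = config$seed * 100L + i)
    truth_by_interval[[i]] <- truth
    rec <- simulate_recruit_counts(truth, iv$cai,
                                   seed = config$seed * 100L + 50L + i)
    if (!length(rec$species)) stop("no recruits simulated; enlarge the stand")
    abun_fit <- abun[rec$species]
    lights <- list()
    for (est in config$light_estimates) {
      lights[[est]] <- switch(est,
        log_cai = light_field(grid$centers$cell_id, iv$log_cai,
                              scale = "log_cai", at = "cell"),
        nci_ts = light_field(grid$centers$cell_id,
                             apply_conversion(conv_ts[[i]], nci_vals[[i]]),
                             scale = "log_cai", at = "cell"),
        nci_tg = light_field(grid$centers$cell_id,
                             apply_conversion(conv_tg, nci_vals[[i]]),
                             scale = "log_cai", at = "cell"),
        nci_raw = light_field(grid$centers$cell_id, nci_vals[[i]],
                              scale = "nci", at = "cell"))
    }
    for (est in config$light_estimates) {
      key <- paste0("interval", i, ".", est)
      fits[[key]] <- fit_recruitment(rec, lights[[est]], abun_fit,
                                     n_chains = config$mcmc$n_chains,
                                     n_burn = config$mcmc$n_burn,
                                     n_sample = config$mcmc$n_sample)
      if (config$classify)
        classifications[[key]] <- classify_species(fits[[key]])
    }
  }

  consistency <- NULL
  if (config$classify && length(classifications) >= 2)
    consistency <- consistency_table(classifications)
  agreement <- NULL
  if (all(c("log_cai", "nci_ts") %in% config$light_estimates))
    agreement <- lapply(seq_len(config$n_intervals), function(i)
      cross_model_agreement(fits[[paste0("interval", i, ".log_cai")]],
                            fits[[paste0("interval", i, ".nci_ts")]]))

  out <- list(grid_search = gs, conversions = list(ts = conv_ts, tg = conv_tg),
              fits = fits, classifications = classifications,
              consistency = consistency, agreement = agreement,
              truth = truth_by_interval, config = config)
  if (!is.null(outdir)) .write_pipeline_outputs(out, outdir)
  out
}

.write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_grid_search(out$grid_search, file.path(outdir, "grid_search.csv"))
  for (key in names(out$fits))
    write.table(out$fits[[key]]$summary,
                file.path(outdir, paste0("summary_", key, ".csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
  for (key in names(out$classifications))
    write.table(out$classifications[[key]],
                file.path(outdir, paste0("classes_", key, ".csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(out$consistency))
    write.table(cbind(criterion = rownames(out$consistency$counts),
                      as.data.frame.matrix(out$consistency$counts)),
                file.path(outdir, "consistency.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  cfg <- out$config
  cfg$stand <- unclass(cfg$stand)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
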