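# Synthetic forest stands, canopy occupancy and demographic
# observations with known ground truth, so every downstream stage can be
# tested for parameter recovery without restricted census data.

#' Stand configuration
#'
#' Targets a stylized old-growth tropical stand: ~32 m2/ha basal area,
#' ~33 m canopy height, log-series species abundances. Diameters are
#' drawn from a shifted Weibull above the 10 mm census threshold (many
#' small stems, a long right tail); positions are uniform or
#' Thomas-process clustered per species (parent points with Gaussian
#' offspring scatter, a standard stylization of dispersal-driven
#' clumping).
#'
#' @param plot_width,plot_height plot dimensions in m.
#' @param basal_area target basal area in m2/ha (default 32).
#' @param canopy_height canopy height cap in m (default 33).
#' @param richness species pool size.
#' @param logseries_x log-series shape in (0, 1); larger values spread
#'   abundance more evenly.
#' @param dbh_shape,dbh_scale Weibull parameters of `dbh - 10` in mm.
#' @param clustering `NULL` for uniform positions, or
#'   `list(parents_per_ha = ..., sigma = ...)` for Thomas clustering.
#' @param seed integer seed making the stand reproducible.
#' @return An object of class `stand_config`.
#' @export
stand_config <- function(plot_width = 100, plot_height = 100,
                         basal_area = 32, canopy_height = 33,
                         richness = 60, logseries_x = 0.98,
                         dbh_shape = 0.85, dbh_scale = 55,
                         clustering = NULL, seed = 1) {
  stopifnot(plot_width > 0, plot_height > 0, basal_area > 0,
            canopy_height > 0, richness >= 1,
            logseries_x > 0, logseries_x < 1, dbh_shape > 0, dbh_scale > 0)
  structure(list(plot_width = plot_width, plot_height = plot_height,
                 basal_area = basal_area, canopy_height = canopy_height,
                 richness = richness, logseries_x = logseries_x,
                 dbh_shape = dbh_shape, dbh_scale = dbh_scale,
                 clustering = clustering, seed = as.integer(seed)),
            class = "stand_config")
}

# log-series counts: P(n) proportional to x^n / n, sampled by inversion
# with an adaptive tail cap
.rlogseries <- function(n, x) {
  nmax <- 1000L
  repeat {
    p <- x^(seq_len(nmax)) / seq_len(nmax)
    if (x^nmax / nmax < 1e-12 * sum(p) || nmax > 1e6) break
    nmax <- nmax * 10L
  }
  sample.int(length(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic census snapshot
#'
#' Species relative abundances follow a log-series; tree count is set so
#' the expected basal area matches the target (redrawn, with the count
#' rescaled, until the realized basal area is within 10% of target;
#' error after 25 attempts). All trees are alive, on their main stem,
#' non-palm.
#'
#' @param config a [stand_config()].
#' @param census_year year recorded in the snapshot.
#' @return A `census_snapshot`.
#' @examples
#' std <- generate_stand(stand_config(seed = 42))
#' sum(pi * (std$trees$dbh / 2000)^2)   # close to 32 m2 on 1 ha
#' @export
generate_stand <- function(config = stand_config(), census_year = 1985) {
  stopifnot(inherits(config, "stand_config"))
  set.seed(config$seed)
  area_ha <- config$plot_width * config$plot_height / 1e4
  target_m2 <- config$basal_area * area_ha
  weights <- .rlogseries(config$richness, config$logseries_x)
  sp_names <- sprintf("sp%03d", seq_len(config$richness))
  # expected basal area per tree (m2) from the Weibull moments
  g2 <- gamma(1 + 2 / config$dbh_shape)
  g1 <- gamma(1 + 1 / config$dbh_shape)
  e_d2 <- 100 + 20 * config$dbh_scale * g1 + config$dbh_scale^2 * g2
  n_trees <- max(round(target_m2 / (pi * e_d2 / 4e6)), config$richness)
  for (attempt in 1:25) {
    dbh <- 10 + rweibull(n_trees, config$dbh_shape, config$dbh_scale)
    ba <- sum(pi * (dbh / 2000)^2)
    if (abs(ba - target_m2) <= 0.1 * target_m2) {
      species <- sample(sp_names, n_trees, replace = TRUE,
                        prob = weights)
      pos <- .draw_positions(n_trees, species, config)
      trees <- data.frame(tree_id = sprintf("t%06d", seq_len(n_trees)),
                          species_id = species, x = pos$x, y = pos$y,
                          dbh = dbh, alive = TRUE, palm = FALSE,
                          main_stem = TRUE, stem_issue = FALSE,
                          stringsAsFactors = FALSE)
      return(census_snapshot(trees, census_year, config$plot_width,
                             config$plot_height))
    }
    n_trees <- max(round(n_trees * target_m2 / ba), config$richness)
  }
  stop("could not reach the basal-area target within 25 attempts; ",
       "the plot may be too small for the configured diameters")
}

.draw_positions <- function(n, species, config) {
  W <- config$plot_width; H <- config$plot_height
  cl <- config$clustering
  if (is.null(cl))
    return(list(x = runif(n, 0, W), y = runif(n, 0, H)))
  stopifnot(is.list(cl), !is.null(cl$parents_per_ha), !is.null(cl$sigma))
  x <- numeric(n); y <- numeric(n)
  for (sp in unique(species)) {
    idx <- which(species == sp)
    n_par <- max(rpois(1, cl$parents_per_ha * W * H / 1e4), 1)
    px <- runif(n_par, 0, W); py <- runif(n_par, 0, H)
    par_of <- sample.int(n_par, length(idx), replace = TRUE)
    x[idx] <- (px[par_of] + rnorm(length(idx), 0, cl$sigma)) %% W
    y[idx] <- (py[par_of] + rnorm(length(idx), 0, cl$sigma)) %% H
  }
  list(x = x, y = y)
}

#' Generate a canopy occupancy census from a stand
#'
#' Each tree's crown is a disk (radius from the crown allometry) whose
#' vertical extent spans the top `crown_depth_frac` of tree height. A
#' layer-cell is occupied iff some crown disk overlaps the cell
#' horizontally and the crown's vertical extent intersects the layer.
#'
#' @param snapshot a `census_snapshot`.
#' @param allometry an [allometry_config()].
#' @param cell_size grid resolution in m (default 5).
#' @return A [canopy_census()] covering the plot.
#' @export
generate_canopy_census <- function(snapshot, allometry = allometry_config(),
                                   cell_size = 5) {
  stopifnot(inherits(snapshot, "census_snapshot"))
  nx <- ceiling(snapshot$plot_width / cell_size)
  ny <- ceiling(snapshot$plot_height / cell_size)
  layers <- array(FALSE, dim = c(nx, ny, 6))
  tr <- snapshot$trees[snapshot$trees$alive, ]
  if (!nrow(tr))
    return(canopy_census(snapshot$census_year, nx, ny, layers,
                         cell_size = cell_size))
  hts <- tree_height(tr$dbh, allometry)
  rad <- crown_radius(tr$dbh, allometry)
  lo <- hts * (1 - allometry$crown_depth_frac)
  for (i in seq_len(nrow(tr))) {
    lay <- which(.layer_lower < hts[i] & .layer_upper > lo[i])
    if (!length(lay)) next
    ix0 <- max(floor((tr$x[i] - rad[i]) / cell_size), 0)
    ix1 <- min(floor((tr$x[i] + rad[i]) / cell_size), nx - 1)
    iy0 <- max(floor((tr$y[i] - rad[i]) / cell_size), 0)
    iy1 <- min(floor((tr$y[i] + rad[i]) / cell_size), ny - 1)
    if (ix1 < ix0 || iy1 < iy0) next
    for (ix in ix0:ix1) {
      # nearest point of the cell rectangle to the stem
      ddx <- pmax(ix * cell_size - tr$x[i], tr$x[i] - (ix + 1) * cell_size, 0)
      for (iy in iy0:iy1) {
        ddy <- pmax(iy * cell_size - tr$y[i], tr$y[i] - (iy + 1) * cell_size, 0)
        if (ddx^2 + ddy^2 <= rad[i]^2)
          layers[ix + 1, iy + 1, lay] <- TRUE
      }
    }
  }
  canopy_census(snapshot$census_year, nx, ny, layers,
                cell_size = cell_size)
}

#' Draw ground-truth species parameters from the hyper-models
#'
#' Recruitment: `a_r, b_r` from the Normal abundance regressions of
#' [recruit_hypers()] and `k` uniform on (0, 100] truncated below at
#' 0.05 (degenerate clumping is numerically unusable). Growth:
#' `a_g, b_g, c` from the regressions of [growth_hypers()] and `d`
#' lognormal with `(delta1, delta2)`.
#'
#' @param hypers a [recruit_hypers()] or [growth_hypers()].
#' @param abundance named species abundance vector.
#' @param seed integer seed.
#' @return data.frame of class `truth_set` with one row per species and
#'   the hyperparameters in `attr(, "hypers")`.
#' @export
draw_species_params <- function(hypers, abundance, seed = 1) {
  set.seed(seed)
  stopifnot(!is.null(names(abundance)), all(abundance >= 1))
  lnab <- log(as.numeric(abundance))
  S <- length(abundance)
  if (inherits(hypers, "recruit_hypers")) {
    h <- as.numeric(hypers)
    out <- data.frame(species = names(abundance), abundance = as.numeric(abundance),
                      a_r = rnorm(S, h[1] + h[2] * lnab, h[3]),
                      b_r = rnorm(S, h[4] + h[5] * lnab, h[6]),
                      k = runif(S, 0.05, 100),
                      stringsAsFactors = FALSE)
  } else if (inherits(hypers, "growth_hypers")) {
    h <- as.numeric(hypers)
    out <- data.frame(species = names(abundance), abundance = as.numeric(abundance),
                      a_g = rnorm(S, h[1] + h[2] * lnab, h[3]),
                      b_g = rnorm(S, h[4] + h[5] * lnab, h[6]),
                      c = rnorm(S, h[7] + h[8] * lnab, h[9]),
                      d = rlnorm(S, h[10], h[11]),
                      stringsAsFactors = FALSE)
  } else stop("hypers must be recruit_hypers or growth_hypers")
  attr(out, "hypers") <- hypers
  attr(out, "seed") <- seed
  class(out) <- c("truth_set", "data.frame")
  out
}

#' Simulate a light field
#'
#' `"latent_lognormal"` draws canopy-index values in (0, 1] whose logs
#' are Normal (upper-truncated at 0, i.e. 100% irradiance); the defaults
#' (median ~2% irradiance, log-sd 0.8) mimic the spread of understorey
#' light in a closed-canopy forest. `"from_canopy"` computes the canopy
#' index on supplied canopy censuses via [cai_for_cells()].
#'
#' @param mode `"latent_lognormal"` or `"from_canopy"`.
#' @param n number of cells (latent mode).
#' @param mu_log,sd_log log-scale mean and sd (latent mode).
#' @param seed integer seed (latent mode).
#' @param censuses,grid,weights,reference passed to [cai_for_cells()]
#'   (from_canopy mode).
#' @return A [light_field()] on the `"cai"` scale.
#' @export
simulate_light_field <- function(mode = c("latent_lognormal", "from_canopy"),
                                 n = NULL, mu_log = log(0.02),
                                 sd_log = 0.8, seed = 1, censuses = NULL,
                                 grid = NULL, weights = shade_weights(),
                                 reference = irradiance_reference()) {
  mode <- match.arg(mode)
  if (mode == "from_canopy") {
    stopifnot(!is.null(censuses), !is.null(grid))
    return(cai_for_cells(censuses, grid, weights, reference))
  }
  stopifnot(!is.null(n), n >= 1, sd_log >= 0)
  set.seed(seed)
  logs <- if (sd_log == 0) rep(min(mu_log, 0), n) else
    qnorm(runif(n) * pnorm(0, mu_log, sd_log), mu_log, sd_log)
  light_field(seq_len(n), exp(logs), scale = "cai", at = "cell")
}

#' Simulate per-cell recruit counts from ground truth
#'
#' `obs_ij ~ NegBinomial(mean = exp(a_rj + b_rj * x_i), clumping k_j)`
#' with `x_i` the centered log light.
#'
#' @param truth a recruitment [draw_species_params()] result.
#' @param light a [light_field()] at cells (or numeric canopy-index
#'   values).
#' @param seed integer seed.
#' @return A `recruit_table` covering all cells.
#' @export
simulate_recruit_counts <- function(truth, light, seed = 1) {
  stopifnot(inherits(truth, "truth_set"), !is.null(truth$a_r))
  lv <- if (inherits(light, "light_field")) model_scale_light(light)
        else log(light)
  x <- lv - mean(lv)
  set.seed(seed)
  n <- length(x)
  rows <- lapply(seq_len(nrow(truth)), function(j) {
    mu <- exp(truth$a_r[j] + truth$b_r[j] * x)
    cnt <- rnbinom(n, size = truth$k[j], mu = mu)
    nz <- which(cnt > 0)
    if (!length(nz)) return(NULL)
    data.frame(cell_id = nz, species_id = truth$species[j],
               count = cnt[nz], stringsAsFactors = FALSE)
  })
  recruit_table(do.call(rbind, c(rows, list(
    data.frame(cell_id = integer(), species_id = character(),
               count = integer())))), n_cells = n)
}

#' Simulate growth observations from ground truth
#'
#' True growth is lognormal around the model prediction (log-sd `d_j`,
#' median equal to the prediction); the observation adds the
#' two-component measurement-error mixture scaled by the interval
#' length.
#'
#' @param truth a growth [draw_species_params()] result.
#' @param light a [light_field()] at trees or numeric canopy-index
#'   values per tree.
#' @param species species id per tree (must appear in `truth`).
#' @param dbh0 initial diameters in mm.
#' @param em an [error_model()].
#' @param interval interval length(s) in years.
#' @param seed integer seed.
#' @return A `growth_records` data.frame with extra columns `true_growth`
#'   and `light` (the canopy-index value used).
#' @export
simulate_growth_observations <- function(truth, light, species, dbh0,
                                         em = error_model(), interval = 5,
                                         seed = 1) {
  stopifnot(inherits(truth, "truth_set"), !is.null(truth$a_g),
            all(species %in% truth$species), all(dbh0 >= 10),
            all(interval > 0))
  n <- length(species)
  lv <- if (inherits(light, "light_field")) model_scale_light(light)
        else log(light)
  stopifnot(length(lv) == n)
  x <- lv - mean(lv)
  int <- rep_len(interval, n)
  set.seed(seed)
  j <- match(species, truth$species)
  pred <- predict_growth(truth$a_g[j], truth$b_g[j], truth$c[j], x, dbh0)
  true <- rlnorm(n, log(pred), truth$d[j])
  gross <- runif(n) < em$f
  sdv <- ifelse(gross, em$sd2, em$s0 + em$s1 * dbh0) / int
  obs <- true + rnorm(n, 0, sdv)
  out <- data.frame(tree_id = sprintf("t%06d", seq_len(n)),
                    species_id = species, dbh0 = dbh0, obs_growth = obs,
                    int = int, true_growth = true, light = exp(lv),
                    stringsAsFactors = FALSE)
  class(out) <- c("growth_records", "data.frame")
  out
}

#' Export a truth set as delimited text
#'
#' @param truth a `truth_set`.
#' @param path output file.
#' @export
write_truth_set <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  write.table(truth, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
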