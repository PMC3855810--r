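# Distance-dependent neighborhood competition indices (NCI), the
# (alpha, beta) grid search against log canopy index, and the
# zero-intercept median quantile-regression conversion onto the
# log(canopy index) scale.

#' NCI configuration
#'
#' The competition index at a focal point is
#' `sum_j dbh_j_cm^alpha / max(dist_ij, floor)^beta` over neighboring
#' trees within `radius` m that are taller than the focal height (when
#' `taller_only`). `alpha` weights neighbor size, `beta` the decay with
#' distance. The distance floor guards against a neighbor coinciding
#' with the focal point.
#'
#' @param alpha,beta non-negative exponents on dbh (cm) and distance (m).
#' @param radius neighborhood radius in m (default 30).
#' @param dist_floor minimum distance in m (default 0.1).
#' @param taller_only count only neighbors taller than the focal height.
#' @param ref_height focal height in m used for grid-cell focal points
#'   (default 2, matching the canopy-index reference height for recruits).
#' @return An object of class `nci_config`.
#' @export
nci_config <- function(alpha, beta, radius = 30, dist_floor = 0.1,
                       taller_only = TRUE, ref_height = 2) {
  stopifnot(alpha >= 0, beta >= 0, radius > 0, dist_floor > 0)
  structure(list(alpha = alpha, beta = beta, radius = radius,
                 dist_floor = dist_floor, taller_only = taller_only,
                 ref_height = ref_height),
            class = "nci_config")
}

# Neighbor lists per focal point: for each focal, the dbh (cm) and
# floored distance (m) of qualifying neighbors. A bucket spatial index
# (bucket width = radius) keeps the scan local; `exclude` removes the
# focal tree itself from its own neighborhood.
nci_profile <- function(x, y, focal_height, snapshot, config,
                        allometry = allometry_config(), exclude = NULL) {
  stopifnot(inherits(snapshot, "census_snapshot"),
            inherits(config, "nci_config"))
  tr <- snapshot$trees[snapshot$trees$alive, ]
  n <- length(x)
  focal_height <- rep_len(focal_height, n)
  if (!is.null(exclude)) exclude <- rep_len(exclude, n)
  if (!nrow(tr))
    return(structure(list(dbh_cm = numeric(), dist = numeric(),
                          point = integer(), n_points = n),
                     class = "nci_profile"))
  hts <- tree_height(tr$dbh, allometry)
  r <- config$radius
  bx <- floor(tr$x / r); by <- floor(tr$y / r)
  key <- paste(bx, by)
  buckets <- split(seq_len(nrow(tr)), key)
  out_dbh <- vector("list", n); out_dist <- vector("list", n)
  for (i in seq_len(n)) {
    fbx <- floor(x[i] / r); fby <- floor(y[i] / r)
    cand <- unlist(buckets[paste(rep(fbx + (-1:1), each = 3),
                                 rep(fby + (-1:1), times = 3))],
                   use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d <- sqrt((tr$x[cand] - x[i])^2 + (tr$y[cand] - y[i])^2)
    sel <- d <= r
    if (config$taller_only) sel <- sel & hts[cand] > focal_height[i]
    if (!is.null(exclude)) sel <- sel & tr$tree_id[cand] != exclude[i]
    if (!any(sel)) next
    out_dbh[[i]] <- tr$dbh[cand][sel] / 10
    out_dist[[i]] <- pmax(d[sel], config$dist_floor)
  }
  lens <- lengths(out_dbh)
  structure(list(dbh_cm = unlist(out_dbh, use.names = FALSE),
                 dist = unlist(out_dist, use.names = FALSE),
                 point = rep(seq_len(n), lens), n_points = n),
            class = "nci_profile")
}

# Evaluate NCI sums for one (alpha, beta) pair on a neighbor profile.
nci_evaluate <- function(profile, alpha, beta) {
  out <- numeric(profile$n_points)
  if (length(profile$dbh_cm)) {
    contrib <- profile$dbh_cm^alpha / profile$dist^beta
    s <- rowsum(contrib, profile$point)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Compute neighborhood competition indices
#'
#' For grid cells the focal point is the cell center with focal height
#' equal to the configured reference height; for trees pass the tree's
#' own allometric height and its id in `exclude` so it does not count as
#' its own neighbor. Neighbors may lie in the plot margin; focal points
#' must lie inside the core region when a `grid` is supplied.
#'
#' @param x,y focal coordinates in m (vectorized).
#' @param focal_height focal height(s) in m.
#' @param snapshot a `census_snapshot` providing the neighbors.
#' @param config an [nci_config()].
#' @param allometry an [allometry_config()] for neighbor heights.
#' @param exclude optional tree id(s) to exclude (the focal trees).
#' @param grid optional [partition_core()] result; if given, focal points
#'   outside the core raise an error.
#' @return Non-negative NCI values (`0^0` counts as 1, so `alpha = beta
#'   = 0` counts qualifying neighbors).
#' @export
compute_nci <- function(x, y, focal_height, snapshot, config,
                        allometry = allometry_config(), exclude = NULL,
                        grid = NULL) {
  if (!is.null(grid)) {
    if (anyNA(cell_of(x, y, grid)))
      stop("focal point outside the core region")
  }
  prof <- nci_profile(x, y, focal_height, snapshot, config, allometry,
                      exclude)
  nci_evaluate(prof, config$alpha, config$beta)
}

#' Grid search for the NCI most correlated with log canopy index
#'
#' Evaluates the Pearson correlation between NCI and log(canopy index)
#' over all `(alpha, beta)` combinations, per census interval and pooled
#' across intervals, and selects the pair with the strongest pooled
#' correlation (largest `|r|`; the correlations are typically negative
#' since more competition means less light). Ties break toward smaller
#' `alpha`, then smaller `beta`; pairs with zero NCI variance are
#' recorded as `NA` and excluded from selection.
#'
#' @param intervals list with one element per census interval, each a
#'   list with `profile` (an internal neighbor profile; see
#'   [nci_profiles_for_cells()]) and `log_light` (log canopy-index values
#'   aligned with the profile's focal points).
#' @param alphas,betas exponent grids (default 0 to 3 in steps of 0.2:
#'   256 combinations).
#' @return An object of class `nci_grid_search`: `$r` (list of per-
#'   interval matrices), `$r_pooled`, `$alpha`, `$beta` (the selected
#'   pair) and `$n_combinations`.
#' @export
nci_grid_search <- function(intervals, alphas = seq(0, 3, by = 0.2),
                            betas = seq(0, 3, by = 0.2)) {
  stopifnot(length(intervals) >= 1)
  for (iv in intervals) {
    stopifnot(inherits(iv$profile, "nci_profile"),
              length(iv$log_light) == iv$profile$n_points)
    if (iv$profile$n_points < 3)
      stop("grid search needs at least 3 focal points per interval")
  }
  dimn <- list(alpha = format(alphas), beta = format(betas))
  r_int <- lapply(intervals, function(iv)
    matrix(NA_real_, length(alphas), length(betas), dimnames = dimn))
  r_pool <- matrix(NA_real_, length(alphas), length(betas), dimnames = dimn)
  y_pool <- unlist(lapply(intervals, `[[`, "log_light"))
  for (ia in seq_along(alphas)) {
    for (ib in seq_along(betas)) {
      ncis <- lapply(intervals, function(iv)
        nci_evaluate(iv$profile, alphas[ia], betas[ib]))
      for (k in seq_along(intervals)) {
        if (sd(ncis[[k]]) > 0)
          r_int[[k]][ia, ib] <- cor(ncis[[k]], intervals[[k]]$log_light)
      }
      x_pool <- unlist(ncis)
      if (sd(x_pool) > 0) r_pool[ia, ib] <- cor(x_pool, y_pool)
    }
  }
  if (all(is.na(r_pool)))
    stop("no (alpha, beta) pair yields a defined correlation")
  # strongest |r|; ties toward smaller alpha, then smaller beta.
  # column-major order of which() scans alpha fastest, matching the
  # tie-break since ties with equal alpha resolve by earlier beta column.
  absr <- abs(r_pool)
  best <- which(absr == max(absr, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(list(alphas = alphas, betas = betas, r = r_int,
                 r_pooled = r_pool,
                 alpha = alphas[best[1]], beta = betas[best[2]],
                 r_best = r_pool[best[1], best[2]],
                 n_combinations = length(alphas) * length(betas)),
            class = "nci_grid_search")
}

#' @export
print.nci_grid_search <- function(x, ...) {
  cat("<nci_grid_search>", x$n_combinations, "combinations; best alpha =",
      x$alpha, ", beta =", x$beta, "(pooled r =", round(x$r_best, 3), ")\n")
  invisible(x)
}

#' Neighbor profiles for grid cells or trees
#'
#' Convenience builders of the neighbor profiles consumed by
#' [nci_grid_search()]: one profile evaluates all `(alpha, beta)` pairs
#' without rescanning neighbors.
#'
#' @param grid a [partition_core()] result (cell centers become focal
#'   points at the configured reference height).
#' @param snapshot the `census_snapshot` providing the neighbors.
#' @param config an [nci_config()] (its `alpha`/`beta` are ignored here).
#' @param allometry an [allometry_config()].
#' @return An internal `nci_profile` object.
#' @export
nci_profiles_for_cells <- function(grid, snapshot,
                                   config = nci_config(1, 1),
                                   allometry = allometry_config()) {
  nci_profile(grid$centers$cx, grid$centers$cy, config$ref_height,
              snapshot, config, allometry)
}

#' @rdname nci_profiles_for_cells
#' @param trees data.frame with `tree_id`, `x`, `y`, `dbh` (focal trees,
#'   e.g. the alive trees of a snapshot or growth records); focal height
#'   is each tree's own allometric height and the tree is excluded from
#'   its own neighborhood.
#' @export
nci_profiles_for_trees <- function(trees, snapshot,
                                   config = nci_config(1, 1),
                                   allometry = allometry_config()) {
  hts <- tree_height(trees$dbh, allometry)
  nci_profile(trees$x, trees$y, hts, snapshot, config, allometry,
              exclude = trees$tree_id)
}

#' Zero-intercept median quantile regression for NCI conversion
#'
#' Fits `logCAI ~ b1 * NCI (+ b2 * NCI^2)` by minimizing the sum of
#' absolute residuals (median regression, tau = 0.5), with the intercept
#' forced to zero so that an empty neighborhood (NCI = 0) maps to full
#' irradiance (log canopy index 0, canopy index 1). Median regression is
#' used because it is robust to the extreme-NCI outliers that arise when
#' a large tree stands next to a focal point. Solved by iteratively
#' reweighted least absolute deviations polished with a direct
#' Nelder-Mead minimization of the L1 objective.
#'
#' @param nci NCI values.
#' @param log_cai log canopy-index values.
#' @param degree 1 (linear, used for grid cells) or 2 (adds a quadratic
#'   term, used for trees where the relationship is curved).
#' @param tau quantile level (default 0.5, the median).
#' @return An object of class `nci_conversion` with coefficients `b1`,
#'   `b2` (0 when `degree = 1`).
#' @export
fit_conversion <- function(nci, log_cai, degree = 1, tau = 0.5) {
  stopifnot(degree %in% c(1, 2), length(nci) == length(log_cai),
            tau > 0, tau < 1)
  if (length(nci) < degree + 1) stop("too few points for the fit")
  if (sd(nci) == 0) stop("degenerate design: all NCI values identical")
  X <- if (degree == 1) cbind(nci) else cbind(nci, nci^2)
  # IRLS for asymmetric L1: weights tau/|r| (r>0) or (1-tau)/|r| (r<0)
  b <- qr.solve(crossprod(X), crossprod(X, log_cai))
  for (it in 1:100) {
    r <- as.numeric(log_cai - X %*% b)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), 1e-8)
    b_new <- qr.solve(crossprod(X, w * X), crossprod(X, w * log_cai))
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  obj <- function(bb) {
    r <- log_cai - X %*% bb
    sum(ifelse(r >= 0, tau, 1 - tau) * abs(r))
  }
  b <- as.numeric(b)
  if (degree == 1) {
    w <- max(1, 10 * abs(b))
    opt <- optimize(function(bb) obj(bb), c(b - w, b + w), tol = 1e-12)
    if (opt$objective <= obj(b)) b <- opt$minimum
  } else {
    opt <- optim(b, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 5000))
    if (opt$value <= obj(b)) b <- opt$par
  }
  structure(list(b1 = b[1], b2 = if (degree == 2) b[2] else 0,
                 degree = degree, tau = tau),
            class = "nci_conversion")
}

#' Apply an NCI-to-log(CAI) conversion
#'
#' Deterministic polynomial evaluation `b1 * NCI + b2 * NCI^2`. Values
#' may fall below the observed log canopy-index range: extreme NCI
#' outliers map to extremely low log canopy-index values.
#'
#' @param conversion a [fit_conversion()] result.
#' @param nci NCI values.
#' @return Values on the log canopy-index scale (`NCI = 0` maps to 0
#'   exactly by the zero-intercept constraint).
#' @export
apply_conversion <- function(conversion, nci) {
  stopifnot(inherits(conversion, "nci_conversion"))
  conversion$b1 * nci + conversion$b2 * nci^2
}

#' Export a grid-search correlation surface
#'
#' Writes the pooled Pearson-r surface as a delimited matrix (rows alpha,
#' columns beta).
#'
#' @param gs an [nci_grid_search()] result.
#' @param path output file.
#' @export
write_grid_search <- function(gs, path) {
  stopifnot(inherits(gs, "nci_grid_search"))
  write.table(cbind(alpha = gs$alphas, gs$r_pooled), path, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
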