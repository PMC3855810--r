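# Canopy index: shade index over layered canopy-occupancy censuses,
# converted to a fraction of full irradiance by quantile matching against
# a reference irradiance distribution.

# fixed height-layer edges (m); layer 6 is open-topped
.layer_lower <- c(0, 2, 5, 10, 20, 30)
.layer_upper <- c(2, 5, 10, 20, 30, Inf)

#' Canopy occupancy census
#'
#' Presence/absence of vegetation in six height layers (0-2, 2-5, 5-10,
#' 10-20, 20-30, >=30 m) on a square grid (default 5 m resolution).
#'
#' @param year census year.
#' @param nx,ny grid dimensions (cells).
#' @param layers logical array `nx x ny x 6`, or `NULL` for an empty
#'   canopy.
#' @param origin grid origin (m).
#' @param cell_size grid resolution in m.
#' @return An object of class `canopy_census`.
#' @export
canopy_census <- function(year, nx, ny, layers = NULL,
                          origin = c(0, 0), cell_size = 5) {
  stopifnot(nx >= 1, ny >= 1, cell_size > 0)
  if (is.null(layers)) layers <- array(FALSE, dim = c(nx, ny, 6))
  stopifnot(identical(dim(layers), c(as.integer(nx), as.integer(ny), 6L)) ||
              identical(dim(layers), c(nx, ny, 6)))
  structure(list(year = as.integer(year), nx = as.integer(nx),
                 ny = as.integer(ny), origin = origin,
                 cell_size = cell_size,
                 layers = array(as.logical(layers), dim = c(nx, ny, 6))),
            class = "canopy_census")
}

#' Shade-index weights
#'
#' The shade index at a focal point is a weighted sum over occupied
#' layer-cells that lie fully above the point and less than `max_dist`
#' m away horizontally. The default horizontal kernel `1/(1 + d)` and
#' unit layer weights are simple monotone choices; both are configurable
#' because published shade indices weight layers and distance in
#' site-specific ways.
#'
#' @param kernel non-negative function of horizontal distance (m).
#' @param layer_weights non-negative weight per height layer (length 6).
#' @param max_dist horizontal support of the kernel in m (default 20).
#' @return An object of class `shade_weights`.
#' @export
shade_weights <- function(kernel = function(d) 1 / (1 + d),
                          layer_weights = rep(1, 6), max_dist = 20) {
  stopifnot(is.function(kernel), length(layer_weights) == 6,
            all(layer_weights >= 0), max_dist > 0)
  structure(list(kernel = kernel, layer_weights = layer_weights,
                 max_dist = max_dist),
            class = "shade_weights")
}

#' Shade index at focal points
#'
#' Sums `kernel(distance) * layer_weight` over occupied layer-cells whose
#' layer lies fully above the reference height (layer lower bound >= h)
#' and whose cell center is within the kernel support of the focal point.
#'
#' @param x,y focal coordinates in m (vectorized).
#' @param h reference height(s) in m: 2 m for grid cells (the height a
#'   recruit must surpass), crown top for trees.
#' @param census a [canopy_census()].
#' @param weights a [shade_weights()].
#' @return Non-negative shade values.
#' @export
shade_index <- function(x, y, h, census, weights = shade_weights()) {
  stopifnot(inherits(census, "canopy_census"), inherits(weights, "shade_weights"))
  n <- length(x)
  h <- rep_len(h, n)
  cs <- census$cell_size
  xmax <- census$origin[1] + census$nx * cs
  ymax <- census$origin[2] + census$ny * cs
  if (any(x < census$origin[1] | x > xmax | y < census$origin[2] | y > ymax))
    stop("focal point outside canopy census extent")
  # per-cell occupancy weight above each possible reference layer cutoff
  ccx <- census$origin[1] + (seq_len(census$nx) - 0.5) * cs
  ccy <- census$origin[2] + (seq_len(census$ny) - 0.5) * cs
  out <- numeric(n)
  maxd <- weights$max_dist
  for (i in seq_len(n)) {
    above <- which(.layer_lower >= h[i])
    if (!length(above)) next
    ix <- which(abs(ccx - x[i]) < maxd)
    iy <- which(abs(ccy - y[i]) < maxd)
    if (!length(ix) || !length(iy)) next
    dx <- ccx[ix] - x[i]
    dy <- ccy[iy] - y[i]
    dist <- sqrt(outer(dx^2, dy^2, "+"))
    near <- dist < maxd
    if (!any(near)) next
    kern <- weights$kernel(dist)
    s <- 0
    for (l in above) {
      occ <- census$layers[ix, iy, l, drop = FALSE]
      dim(occ) <- dim(near)
      sel <- occ & near
      if (any(sel)) s <- s + weights$layer_weights[l] * sum(kern[sel])
    }
    out[i] <- s
  }
  out
}

#' Reference irradiance distribution
#'
#' A parametric distribution of relative irradiance on (0, 1] used as the
#' target of quantile matching. The default is a lognormal truncated at 1
#' with median ~2% of full irradiance, a configurable synthetic stand-in
#' for published understorey irradiance measurements.
#'
#' @param meanlog,sdlog lognormal parameters on the log-irradiance scale.
#' @return An object of class `irradiance_reference` with a quantile
#'   function `$quantile`.
#' @export
irradiance_reference <- function(meanlog = log(0.02), sdlog = 1) {
  stopifnot(sdlog >= 0)
  p1 <- if (sdlog == 0) 1 else plnorm(1, meanlog, sdlog)
  qf <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    if (sdlog == 0) return(rep(min(exp(meanlog), 1), length(p)))
    pmin(qlnorm(p * p1, meanlog, sdlog), 1)
  }
  structure(list(meanlog = meanlog, sdlog = sdlog, quantile = qf),
            class = "irradiance_reference")
}

#' Calibrate shade against a reference irradiance distribution
#'
#' Rank-based quantile matching: a shade value at empirical quantile `q`
#' (plotting position `(rank - 0.5) / n`, average ranks for ties) is
#' mapped to the reference distribution's `1 - q` quantile, so the most
#' shaded point receives the least light. The resulting monotone
#' decreasing mapping can be applied to new shade values (e.g. at tree
#' crowns) by interpolation.
#'
#' @param shades shade values at the calibration points (the 2 m grid-cell
#'   shades); at least two distinct values required.
#' @param reference an [irradiance_reference()].
#' @return An object of class `shade_calibration`.
#' @export
calibrate_shade <- function(shades, reference = irradiance_reference()) {
  stopifnot(inherits(reference, "irradiance_reference"), length(shades) >= 2)
  if (length(unique(shades)) < 2)
    stop("all shade values identical; calibration mapping is degenerate")
  n <- length(shades)
  q <- (rank(shades, ties.method = "average") - 0.5) / n
  ord <- order(shades)
  su <- shades[ord]; qu <- q[ord]
  keep <- !duplicated(su)
  structure(list(shade = su[keep], q = qu[keep], n = n,
                 reference = reference),
            class = "shade_calibration")
}

#' Apply a shade calibration
#'
#' @param object a [calibrate_shade()] result.
#' @param shades new shade values.
#' @param ... unused.
#' @return Canopy-index values in (0, 1], decreasing in shade. Shade
#'   values outside the calibrated range take the boundary quantiles.
#' @export
predict.shade_calibration <- function(object, shades, ...) {
  q <- if (length(object$shade) == 1L) {
    rep(object$q, length(shades))
  } else {
    approx(object$shade, object$q, xout = shades, rule = 2)$y
  }
  # keep mapped quantiles strictly inside (0, 1)
  q <- pmin(pmax(q, 0.5 / object$n), 1 - 0.5 / object$n)
  object$reference$quantile(1 - q)
}

#' Canopy index for grid cells or trees
#'
#' For each yearly canopy census, shade is computed at every focal point,
#' calibrated against the reference distribution via the 2 m grid-cell
#' shades of that year, and mapped to a canopy index; yearly indices are
#' then averaged arithmetically over the census interval. Grid cells use
#' the cell center at 2 m reference height; trees use their position at
#' allometric crown-top height (a tree taller than every occupied layer
#' simply receives zero shade, i.e. full light).
#'
#' @param censuses list of [canopy_census()] objects (the yearly censuses
#'   of one interval).
#' @param grid a [partition_core()] result.
#' @param weights a [shade_weights()].
#' @param reference an [irradiance_reference()].
#' @param ref_height reference height for cells in m (default 2).
#' @return A [light_field()] on the `"cai"` scale.
#' @export
cai_for_cells <- function(censuses, grid, weights = shade_weights(),
                          reference = irradiance_reference(),
                          ref_height = 2) {
  stopifnot(length(censuses) >= 1, inherits(grid, "grid_spec"))
  vals <- vapply(censuses, function(cc) {
    sh <- shade_index(grid$centers$cx, grid$centers$cy, ref_height, cc, weights)
    cal <- calibrate_shade(sh, reference)
    predict(cal, sh)
  }, numeric(nrow(grid$centers)))
  light_field(grid$centers$cell_id, rowMeans(as.matrix(vals)),
              scale = "cai", at = "cell")
}

#' @rdname cai_for_cells
#' @param snapshot a `census_snapshot`; the canopy index is computed for
#'   its alive trees.
#' @param allometry an [allometry_config()] for crown-top heights.
#' @param ref_height_cells reference height (m) of the grid-cell shades
#'   used for calibration.
#' @export
cai_for_trees <- function(snapshot, allometry, censuses, grid,
                          weights = shade_weights(),
                          reference = irradiance_reference(),
                          ref_height_cells = 2) {
  stopifnot(inherits(snapshot, "census_snapshot"), length(censuses) >= 1)
  tr <- snapshot$trees[snapshot$trees$alive, ]
  hts <- tree_height(tr$dbh, allometry)
  vals <- vapply(censuses, function(cc) {
    sh_cells <- shade_index(grid$centers$cx, grid$centers$cy,
                            ref_height_cells, cc, weights)
    cal <- calibrate_shade(sh_cells, reference)
    sh_trees <- shade_index(tr$x, tr$y, hts, cc, weights)
    predict(cal, sh_trees)
  }, numeric(nrow(tr)))
  light_field(tr$tree_id, rowMeans(as.matrix(vals)),
              scale = "cai", at = "tree")
}

#' Read or write a canopy census file
#'
#' Delimited text (comma or tab autodetected) with columns `year`,
#' `cell_x`, `cell_y` (0-based cell indices) and `L1`..`L6` (0/1
#' occupancy per height layer).
#'
#' @param path file path.
#' @param nx,ny,origin,cell_size grid geometry (see [canopy_census()]).
#' @return [read_canopy_census()] returns a list of `canopy_census`, one
#'   per year in the file; [write_canopy_census()] returns `path`.
#' @export
read_canopy_census <- function(path, nx, ny, origin = c(0, 0),
                               cell_size = 5) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep)
  want <- c("year", "cell_x", "cell_y", paste0("L", 1:6))
  missing <- setdiff(want, names(raw))
  if (length(missing))
    stop("canopy census file missing columns: ",
         paste(missing, collapse = ", "))
  if (any(raw$cell_x < 0 | raw$cell_x >= nx |
          raw$cell_y < 0 | raw$cell_y >= ny))
    stop("cell indices outside grid")
  lapply(split(raw, raw$year), function(d) {
    layers <- array(FALSE, dim = c(nx, ny, 6))
    for (l in 1:6) {
      on <- d[d[[paste0("L", l)]] != 0, ]
      if (nrow(on))
        layers[cbind(on$cell_x + 1L, on$cell_y + 1L, l)] <- TRUE
    }
    canopy_census(d$year[1], nx, ny, layers, origin, cell_size)
  })
}

#' @rdname read_canopy_census
#' @param censuses list of `canopy_census` objects.
#' @export
write_canopy_census <- function(censuses, path) {
  if (inherits(censuses, "canopy_census")) censuses <- list(censuses)
  rows <- lapply(censuses, function(cc) {
    idx <- expand.grid(cell_x = seq_len(cc$nx) - 1L,
                       cell_y = seq_len(cc$ny) - 1L)
    occ <- sapply(1:6, function(l)
      as.integer(cc$layers[cbind(idx$cell_x + 1L, idx$cell_y + 1L, l)]))
    colnames(occ) <- paste0("L", 1:6)
    cbind(data.frame(year = cc$year), idx, as.data.frame(occ))
  })
  write.table(do.call(rbind, rows), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
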