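#' Allometry configuration
#'
#' Power-law allometries linking stem diameter to tree height and crown
#' size. Height is `h0 * dbh_cm^h1`, capped at the canopy height; crown
#' radius is `r0 * dbh_cm^r1`; the crown occupies the top
#' `crown_depth_frac` fraction of tree height. The coefficients are
#' deliberately simple and configurable: they are a stylized stand-in for
#' site-specific allometries, not estimates from any particular plot.
#'
#' @param h0,h1 height coefficients (height in m for dbh in cm).
#' @param height_cap maximum tree height in m (default 33, a typical
#'   old-growth tropical canopy height).
#' @param r0,r1 crown-radius coefficients (radius in m for dbh in cm).
#' @param crown_depth_frac fraction of tree height occupied by the crown.
#' @return An object of class `allometry_config`.
#' @examples
#' al <- allometry_config()
#' tree_height(100, al)  # a 10 cm dbh tree
#' @export
allometry_config <- function(h0 = 1.5, h1 = 0.7, height_cap = 33,
                             r0 = 0.5, r1 = 0.6, crown_depth_frac = 0.3) {
  stopifnot(h0 > 0, h1 > 0, height_cap > 0, r0 > 0, r1 >= 0,
            crown_depth_frac > 0, crown_depth_frac <= 1)
  structure(list(h0 = h0, h1 = h1, height_cap = height_cap,
                 r0 = r0, r1 = r1, crown_depth_frac = crown_depth_frac),
            class = "allometry_config")
}

#' Allometric tree height
#'
#' @param dbh_mm stem diameter in mm.
#' @param allometry an [allometry_config()].
#' @return Height in m, capped at the configured canopy height.
#' @export
tree_height <- function(dbh_mm, allometry = allometry_config()) {
  stopifnot(all(dbh_mm > 0))
  pmin(allometry$h0 * (dbh_mm / 10)^allometry$h1, allometry$height_cap)
}

#' Allometric crown radius
#'
#' @inheritParams tree_height
#' @return Crown radius in m.
#' @export
crown_radius <- function(dbh_mm, allometry = allometry_config()) {
  stopifnot(all(dbh_mm > 0))
  allometry$r0 * (dbh_mm / 10)^allometry$r1
}
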