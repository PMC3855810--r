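# Census containers, file I/O and the deterministic data-preparation
# rules: core-region gridding, diameter rounding, recruit extraction and
# growth-record extraction.

.tree_cols <- c("tree_id", "species_id", "x", "y", "dbh", "alive",
                "palm", "main_stem", "stem_issue")

#' Construct a census snapshot
#'
#' A snapshot holds every tagged tree of one census: identity, species,
#' position (m), stem diameter at breast height (dbh, mm), and the flags
#' needed by the growth-data rules. Alive trees must have dbh >= 10 mm
#' (the census inclusion threshold of 1 cm) and lie inside the plot.
#'
#' @param trees data.frame with columns `tree_id`, `species_id`, `x`, `y`,
#'   `dbh`, `alive`, `palm`, `main_stem`, `stem_issue`. `dbh` may be NA
#'   for dead trees.
#' @param census_year integer census year.
#' @param plot_width,plot_height plot dimensions in m.
#' @return An object of class `census_snapshot`.
#' @export
census_snapshot <- function(trees, census_year, plot_width, plot_height) {
  stopifnot(is.data.frame(trees), plot_width > 0, plot_height > 0)
  missing <- setdiff(.tree_cols, names(trees))
  if (length(missing))
    stop("trees is missing columns: ", paste(missing, collapse = ", "))
  trees <- trees[, .tree_cols]
  trees$tree_id <- as.character(trees$tree_id)
  trees$species_id <- as.character(trees$species_id)
  for (fl in c("alive", "palm", "main_stem", "stem_issue"))
    trees[[fl]] <- as.logical(trees[[fl]])
  if (anyDuplicated(trees$tree_id))
    stop("duplicate tree_id in snapshot: ",
         paste(unique(trees$tree_id[duplicated(trees$tree_id)]), collapse = ", "))
  if (any(trees$x < 0 | trees$x > plot_width |
          trees$y < 0 | trees$y > plot_height, na.rm = TRUE))
    stop("tree coordinates outside plot bounds")
  bad <- trees$alive & (is.na(trees$dbh) | trees$dbh < 10)
  if (any(bad))
    stop("alive trees must have dbh >= 10 mm; offending tree_id: ",
         paste(head(trees$tree_id[bad], 5), collapse = ", "))
  structure(list(census_year = as.integer(census_year),
                 plot_width = plot_width, plot_height = plot_height,
                 trees = trees),
            class = "census_snapshot")
}

#' @export
print.census_snapshot <- function(x, ...) {
  cat("<census_snapshot>", x$census_year, ":", nrow(x$trees), "trees (",
      sum(x$trees$alive), "alive ) on", x$plot_width, "x", x$plot_height,
      "m\n")
  invisible(x)
}

#' Pair two censuses into an interval
#'
#' @param start,end `census_snapshot` objects sharing plot geometry; `end`
#'   must be the later census.
#' @param interval_years interval length(s) in years: a scalar applied to
#'   every tree, or a vector named by `tree_id` (remeasurement dates can
#'   differ between trees). Defaults to the difference in census years.
#' @return An object of class `census_interval`.
#' @export
census_interval <- function(start, end, interval_years = NULL) {
  stopifnot(inherits(start, "census_snapshot"), inherits(end, "census_snapshot"))
  if (end$census_year <= start$census_year)
    stop("end census must be later than start census")
  if (start$plot_width != end$plot_width || start$plot_height != end$plot_height)
    stop("censuses do not share plot geometry")
  if (is.null(interval_years))
    interval_years <- end$census_year - start$census_year
  if (any(interval_years <= 0)) stop("interval lengths must be positive")
  structure(list(start = start, end = end, interval_years = interval_years),
            class = "census_interval")
}

#' Read or write a census file
#'
#' Delimited text (comma or tab, autodetected from the header line) with
#' columns `tree_id, species, x, y, dbh_mm, status, palm, main_stem,
#' stem_issue`; `status` is `alive`/`dead`, flags are 0/1. Malformed
#' numeric fields are reported with their row numbers.
#'
#' @param path file path.
#' @param census_year,plot_width,plot_height snapshot metadata (the file
#'   stores the tree table only).
#' @return [read_census()] returns a `census_snapshot`; [write_census()]
#'   returns `path` invisibly.
#' @examples
#' f <- system.file("extdata", "example_census_1985.csv",
#'                  package = "treelight")
#' read_census(f, 1985, 40, 40)
#' @export
read_census <- function(path, census_year, plot_width, plot_height) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", stringsAsFactors = FALSE)
  want <- c("tree_id", "species", "x", "y", "dbh_mm", "status",
            "palm", "main_stem", "stem_issue")
  missing <- setdiff(want, names(raw))
  if (length(missing))
    stop("census file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) &
                   !(raw[[col]] %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric '", col, "' in ", path, " at data row(s): ",
           paste(head(bad, 10), collapse = ", "))
    v
  }
  if (anyDuplicated(raw$tree_id))
    stop("duplicate tree_id in ", path, ": ",
         paste(unique(raw$tree_id[duplicated(raw$tree_id)]), collapse = ", "))
  bad_status <- which(!raw$status %in% c("alive", "dead"))
  if (length(bad_status))
    stop("status must be 'alive' or 'dead' in ", path, " at data row(s): ",
         paste(head(bad_status, 10), collapse = ", "))
  trees <- data.frame(tree_id = raw$tree_id, species_id = raw$species,
                      x = num("x"), y = num("y"), dbh = num("dbh_mm"),
                      alive = raw$status == "alive",
                      palm = num("palm") != 0,
                      main_stem = num("main_stem") != 0,
                      stem_issue = num("stem_issue") != 0,
                      stringsAsFactors = FALSE)
  census_snapshot(trees, census_year, plot_width, plot_height)
}

#' @rdname read_census
#' @param snapshot a `census_snapshot`.
#' @param sep field separator, `","` or `"\t"`.
#' @export
write_census <- function(snapshot, path, sep = ",") {
  stopifnot(inherits(snapshot, "census_snapshot"), sep %in% c(",", "\t"))
  tr <- snapshot$trees
  out <- data.frame(tree_id = tr$tree_id, species = tr$species_id,
                    x = tr$x, y = tr$y, dbh_mm = tr$dbh,
                    status = ifelse(tr$alive, "alive", "dead"),
                    palm = as.integer(tr$palm),
                    main_stem = as.integer(tr$main_stem),
                    stem_issue = as.integer(tr$stem_issue))
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Partition the plot core into grid cells
#'
#' Strips a margin from each side of the plot (to avoid edge effects in
#' neighborhood computations) and tiles the remaining core region with
#' square cells. Cells are half-open `[x0, x0 + cell)` so every position
#' falls in exactly one cell; ids are row-major from the core origin
#' (x fastest).
#'
#' @param plot_width,plot_height plot dimensions in m.
#' @param margin margin width in m stripped from each side (default 30).
#' @param cell_size cell edge length in m (default 5).
#' @return An object of class `grid_spec` with the cell centers in
#'   `$centers` (`cell_id`, `cx`, `cy`).
#' @examples
#' g <- partition_core(1000, 500)   # 188 x 88 = 16544 cells
#' nrow(g$centers)
#' @export
partition_core <- function(plot_width, plot_height, margin = 30,
                           cell_size = 5) {
  stopifnot(plot_width > 0, plot_height > 0, margin >= 0, cell_size > 0)
  core_w <- plot_width - 2 * margin
  core_h <- plot_height - 2 * margin
  if (core_w <= 0 || core_h <= 0) stop("margin leaves no core region")
  nx <- core_w / cell_size
  ny <- core_h / cell_size
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("core dimensions (", core_w, " x ", core_h,
         ") are not divisible by cell_size ", cell_size)
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  cx <- margin + (seq_len(nx) - 0.5) * cell_size
  cy <- margin + (seq_len(ny) - 0.5) * cell_size
  centers <- data.frame(cell_id = seq_len(nx * ny),
                        cx = rep(cx, times = ny),
                        cy = rep(cy, each = nx))
  structure(list(cell_size = cell_size, margin = margin,
                 origin = c(margin, margin), nx = nx, ny = ny,
                 core_width = core_w, core_height = core_h,
                 plot_width = plot_width, plot_height = plot_height,
                 centers = centers),
            class = "grid_spec")
}

#' Map positions to core grid cells
#'
#' @param x,y coordinates in m.
#' @param grid a [partition_core()] result.
#' @return Integer cell ids; `NA` for positions outside the core.
#' @export
cell_of <- function(x, y, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ix <- floor((x - grid$origin[1]) / grid$cell_size)
  iy <- floor((y - grid$origin[2]) / grid$cell_size)
  ok <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(iy[ok] * grid$nx + ix[ok] + 1L)
  out
}

#' Round small diameters down to the nearest 5 mm
#'
#' Emulates the historical field protocol in which stems below 55 mm were
#' recorded to the nearest lower 5 mm in one census. Diameters >= 55 mm
#' are returned unchanged.
#'
#' @param dbh_mm positive diameters in mm.
#' @return Rounded diameters in mm.
#' @examples
#' apply_rounding(c(52, 54.9, 55, 57))  # 50 50 55 57
#' @export
apply_rounding <- function(dbh_mm) {
  if (any(dbh_mm <= 0, na.rm = TRUE)) stop("dbh must be positive")
  ifelse(!is.na(dbh_mm) & dbh_mm < 55, 5 * floor(dbh_mm / 5), dbh_mm)
}

#' Extract per-cell per-species recruit counts
#'
#' A recruit is a tree absent (or dead) at the start census and alive with
#' dbh >= 10 mm at the end census, i.e. a stem that crossed the 1 cm
#' inclusion threshold during the interval. Recruits are counted per core
#' grid cell and species; trees in the margin are excluded from the
#' counts.
#'
#' @param interval a [census_interval()].
#' @param grid a [partition_core()] result matching the plot geometry.
#' @return An object of class `recruit_table`: data.frame `$counts`
#'   (`cell_id`, `species_id`, `count`; only non-zero rows), with the full
#'   cell set implied by `grid` (zeros implicit) and `$species` the
#'   species with at least one recruit.
#' @export
extract_recruits <- function(interval, grid) {
  stopifnot(inherits(interval, "census_interval"), inherits(grid, "grid_spec"))
  if (grid$plot_width != interval$start$plot_width ||
      grid$plot_height != interval$start$plot_height)
    stop("grid does not match plot geometry")
  st <- interval$start$trees
  en <- interval$end$trees
  present_start <- st$tree_id[st$alive]
  rec <- en[en$alive & en$dbh >= 10 & !(en$tree_id %in% present_start), ,
            drop = FALSE]
  if (any(rec$x < 0 | rec$x > grid$plot_width |
          rec$y < 0 | rec$y > grid$plot_height))
    stop("recruit coordinates outside plot bounds")
  cell <- cell_of(rec$x, rec$y, grid)
  keep <- !is.na(cell)
  rec <- rec[keep, , drop = FALSE]
  cell <- cell[keep]
  if (nrow(rec)) {
    counts <- aggregate(list(count = rep(1L, nrow(rec))),
                        by = list(cell_id = cell, species_id = rec$species_id),
                        FUN = sum)
    counts <- counts[order(counts$species_id, counts$cell_id), ]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(cell_id = integer(), species_id = character(),
                         count = integer())
  }
  recruit_table(counts, n_cells = nrow(grid$centers))
}

#' Construct a recruit table
#'
#' @param counts data.frame (`cell_id`, `species_id`, `count`); zero rows
#'   may be omitted (implicit zeros).
#' @param n_cells total number of core cells.
#' @return An object of class `recruit_table`.
#' @export
recruit_table <- function(counts, n_cells) {
  stopifnot(is.data.frame(counts),
            all(c("cell_id", "species_id", "count") %in% names(counts)),
            n_cells >= 1)
  if (any(counts$count < 0)) stop("recruit counts must be non-negative")
  if (any(counts$cell_id < 1 | counts$cell_id > n_cells))
    stop("cell_id outside grid")
  counts <- counts[counts$count > 0, , drop = FALSE]
  structure(list(counts = counts, n_cells = as.integer(n_cells),
                 species = sort(unique(counts$species_id))),
            class = "recruit_table")
}

#' Dense count matrix of a recruit table
#'
#' @param x a `recruit_table`.
#' @param ... unused.
#' @return Integer matrix cells x species (implicit zeros filled in).
#' @export
as.matrix.recruit_table <- function(x, ...) {
  sp <- x$species
  Y <- matrix(0L, nrow = x$n_cells, ncol = length(sp),
              dimnames = list(NULL, sp))
  if (nrow(x$counts))
    Y[cbind(x$counts$cell_id, match(x$counts$species_id, sp))] <-
      as.integer(x$counts$count)
  Y
}

#' Extract annualized growth records
#'
#' Keeps trees alive in both censuses, on their main stem, excluding
#' palms (no secondary growth) and stems with measurement-position issues
#' (moved point of measure, broken-and-resprouted stems). Growth is the
#' dbh increment divided by the interval length (mm/yr) and may be
#' negative. With `use_rounding = TRUE` both census diameters below 55 mm
#' are floored to 5 mm multiples before differencing, emulating the
#' protocol of intervals in which the first census recorded small stems
#' rounded down.
#'
#' @param interval a [census_interval()].
#' @param use_rounding apply [apply_rounding()] to both diameters.
#' @return data.frame of class `growth_records` with columns `tree_id`,
#'   `species_id`, `dbh0` (mm, start diameter as used), `obs_growth`
#'   (mm/yr), `int` (yr).
#' @export
extract_growth_records <- function(interval, use_rounding = FALSE) {
  stopifnot(inherits(interval, "census_interval"))
  st <- interval$start$trees
  en <- interval$end$trees
  m <- merge(st[st$alive, c("tree_id", "species_id", "x", "y", "dbh")],
             en[en$alive, c("tree_id", "dbh", "palm", "main_stem",
                            "stem_issue")],
             by = "tree_id", suffixes = c("0", "1"))
  m <- m[m$main_stem & !m$palm & !m$stem_issue, , drop = FALSE]
  iv <- interval$interval_years
  int <- if (length(iv) == 1L) rep(iv, nrow(m)) else {
    ints <- iv[m$tree_id]
    if (any(is.na(ints))) stop("missing interval length for some trees")
    unname(ints)
  }
  if (any(int <= 0)) stop("interval lengths must be positive")
  d0 <- m$dbh0; d1 <- m$dbh1
  if (use_rounding) { d0 <- apply_rounding(d0); d1 <- apply_rounding(d1) }
  out <- data.frame(tree_id = m$tree_id, species_id = m$species_id,
                    x = m$x, y = m$y, dbh0 = d0,
                    obs_growth = (d1 - d0) / int, int = int,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tree_id), ]
  rownames(out) <- NULL
  class(out) <- c("growth_records", "data.frame")
  out
}

#' Species abundance at a census
#'
#' Counts alive individuals per species over the whole plot (margin
#' included): abundance is a plot-level property even though recruit
#' counts are restricted to the core.
#'
#' @param snapshot a `census_snapshot`.
#' @return Named integer vector, species -> count of alive trees.
#' @export
compute_abundance <- function(snapshot) {
  stopifnot(inherits(snapshot, "census_snapshot"))
  tr <- snapshot$trees[snapshot$trees$alive, ]
  if (!nrow(tr)) return(setNames(integer(0), character(0)))
  tab <- table(tr$species_id)
  setNames(as.integer(tab), names(tab))
}

#' Light-field container
#'
#' A light proxy evaluated at a set of focal points (grid cells or trees):
#' canopy index (`"cai"`, fraction of full irradiance in (0,1]), its log
#' (`"log_cai"`), or a raw/converted neighborhood competition index
#' (`"nci"` / `"log_cai"` after conversion).
#'
#' @param id focal-point identifiers (cell ids or tree ids).
#' @param value light values.
#' @param scale one of `"cai"`, `"log_cai"`, `"nci"`.
#' @param at one of `"cell"`, `"tree"`.
#' @return data.frame of class `light_field`.
#' @export
light_field <- function(id, value, scale = c("cai", "log_cai", "nci"),
                        at = c("cell", "tree")) {
  scale <- match.arg(scale)
  at <- match.arg(at)
  stopifnot(length(id) == length(value), all(is.finite(value)))
  if (scale == "cai" && any(value <= 0 | value > 1))
    stop("canopy-index values must lie in (0, 1]")
  out <- data.frame(id = id, value = value, stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  attr(out, "at") <- at
  class(out) <- c("light_field", "data.frame")
  out
}

# Light values on the (log) scale used by the demographic models:
# log(CAI) for canopy-index fields, the values as-is for NCI-scale fields
# (already on the log(CAI) scale after conversion, or raw by request).
model_scale_light <- function(lf) {
  stopifnot(inherits(lf, "light_field"))
  if (attr(lf, "scale") == "cai") log(lf$value) else lf$value
}
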