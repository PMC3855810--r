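test_that("census files round-trip and malformed input is diagnosed", {
  trees <- mk_trees(c("t1", "t2", "t3"), c("spA", "spA", "spB"),
                    x = c(10, 20, 30), y = c(15, 25, 35),
                    dbh = c(100, 52, 340))
  snap <- mk_snapshot(trees)
  path <- withr::local_tempfile(fileext = ".csv")
  write_census(snap, path)
  back <- read_census(path, 1985, 100, 100)
  expect_equal(back$trees, snap$trees)
  expect_equal(back$census_year, snap$census_year)

  # tab-separated files are autodetected
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_census(snap, path2, sep = "\t")
  expect_equal(read_census(path2, 1985, 100, 100)$trees, snap$trees)

  # non-numeric dbh is reported with its row number
  lines <- readLines(path)
  lines[3] <- sub("52", "abc", lines[3])
  writeLines(lines, path)
  expect_error(read_census(path, 1985, 100, 100), "row.*2")

  # an empty file with a valid header yields an empty snapshot
  writeLines(lines[1], path)
  empty <- read_census(path, 1985, 100, 100)
  expect_equal(nrow(empty$trees), 0)
})

test_that("snapshot invariants are enforced", {
  expect_error(mk_snapshot(mk_trees(c("t1", "t1"), x = c(1, 2))),
               "duplicate")
  expect_error(mk_snapshot(mk_trees("t1", x = 150)), "bounds")
  expect_error(mk_snapshot(mk_trees("t1", dbh = 5)), "dbh")
  expect_error(mk_snapshot(mk_trees("t1")[, -5]), "missing columns")
  # dead trees may have NA dbh
  tr <- mk_trees(c("t1", "t2"), x = c(1, 2), dbh = c(100, NA),
                 alive = c(TRUE, FALSE))
  expect_s3_class(mk_snapshot(tr), "census_snapshot")
})

test_that("core gridding tiles exactly and rejects non-divisible plots", {
  g <- partition_core(1000, 500, 30, 5)
  expect_equal(nrow(g$centers), 16544L)
  expect_equal(c(g$nx, g$ny), c(188L, 88L))
  expect_equal(nrow(partition_core(10, 10, 0, 5)$centers), 4L)
  expect_error(partition_core(12, 10, 0, 5), "divisible")
  expect_error(partition_core(50, 50, 25, 5), "core")

  # cells are half-open: boundary positions fall in exactly one cell
  expect_equal(cell_of(c(30, 34.999, 35), c(30, 30, 30), g),
               c(1L, 1L, 2L))
  expect_true(is.na(cell_of(29.9, 50, g)))
  expect_true(is.na(cell_of(970, 50, g)))
  # centers are cell midpoints
  expect_equal(g$centers$cx[1:2], c(32.5, 37.5))
  expect_equal(cell_of(g$centers$cx, g$centers$cy, g), g$centers$cell_id)
})

test_that("diameter rounding floors small stems only", {
  expect_equal(apply_rounding(52), 50)
  expect_equal(apply_rounding(54.9), 50)
  expect_equal(apply_rounding(55), 55)
  expect_equal(apply_rounding(57), 57)
  expect_equal(apply_rounding(c(10, 12.5, 54.999, 200)),
               c(10, 10, 50, 200))
  expect_error(apply_rounding(0), "positive")
})

test_that("recruit extraction applies presence, threshold and margin rules", {
  g <- partition_core(100, 100, 30, 5)
  start <- mk_snapshot(mk_trees(c("t1", "t2"),
                                x = c(50, 50), y = c(50, 55),
                                dbh = c(100, 30),
                                alive = c(TRUE, FALSE)))
  # t3 is new in the core; t4 is new but in the margin; t2 was dead
  # before (counts as recruit); t1 survives (not a recruit)
  end <- mk_snapshot(mk_trees(c("t1", "t2", "t3", "t4"),
                              c("spA", "spA", "spB", "spB"),
                              x = c(50, 50, 52, 10),
                              y = c(50, 55, 52, 50),
                              dbh = c(110, 30, 12, 14)), year = 1990)
  rt <- extract_recruits(census_interval(start, end), g)
  expect_equal(sum(rt$counts$count), 2)
  expect_setequal(rt$species, c("spA", "spB"))
  expect_setequal(rt$counts$cell_id, cell_of(c(50, 52), c(55, 52), g))
  Y <- as.matrix(rt)
  expect_equal(dim(Y), c(nrow(g$centers), 2L))
  expect_equal(sum(Y), 2)
})

test_that("growth records honor exclusion flags and the rounding rule", {
  start <- mk_snapshot(mk_trees(c("t1", "t2", "t3", "t4", "t5"),
                                x = 1:5, y = 1:5,
                                dbh = c(52, 100, 60, 70, 80)))
  end <- mk_snapshot(mk_trees(c("t1", "t2", "t3", "t4", "t5"),
                              x = 1:5, y = 1:5,
                              dbh = c(53, 110, 65, 75, 85),
                              palm = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                              main_stem = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                              stem_issue = c(FALSE, FALSE, FALSE, FALSE,
                                             TRUE)),
                      year = 1990)
  iv <- census_interval(start, end)
  gr <- extract_growth_records(iv)
  # palm, non-main-stem and stem-issue trees are dropped
  expect_setequal(gr$tree_id, c("t1", "t2"))
  expect_equal(gr$obs_growth[gr$tree_id == "t2"], 2)
  expect_equal(gr$obs_growth[gr$tree_id == "t1"], 0.2)
  # with rounding both small diameters floor to 50: zero growth
  gr_r <- extract_growth_records(iv, use_rounding = TRUE)
  expect_equal(gr_r$obs_growth[gr_r$tree_id == "t1"], 0)
  expect_equal(gr_r$dbh0[gr_r$tree_id == "t1"], 50)
  # large stems are unaffected by the rounding flag
  expect_equal(gr_r$obs_growth[gr_r$tree_id == "t2"], 2)
  # order independence: shuffling rows changes nothing
  start2 <- mk_snapshot(start$trees[5:1, ])
  gr2 <- extract_growth_records(census_interval(start2, end))
  expect_equal(gr2, gr)
})

test_that("abundance counts alive trees per species over the whole plot", {
  snap <- mk_snapshot(mk_trees(paste0("t", 1:5),
                               c("spA", "spA", "spA", "spB", "spA"),
                               x = 1:5, y = 1:5,
                               alive = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  ab <- compute_abundance(snap)
  expect_equal(ab[["spA"]], 3L)
  expect_equal(ab[["spB"]], 1L)
  expect_equal(sum(ab), sum(snap$trees$alive))
  empty <- mk_snapshot(mk_trees(character(), x = numeric(), y = numeric(),
                                dbh = numeric(), species_id = character(),
                                alive = logical(), palm = logical(),
                                main_stem = logical(),
                                stem_issue = logical()))
  expect_length(compute_abundance(empty), 0)
})
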