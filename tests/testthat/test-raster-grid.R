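test_that("grid_spec validates its fields and alignment semantics", {
  expect_error(grid_spec(0, 0, -1, 2, 2), "pixel_size")
  expect_error(grid_spec(0, 0, 30, 0, 2), "positive integers")

  a <- grid_spec(0, 300, 30, 10, 10)
  b <- grid_spec(90, 150, 30, 5, 5)        # offset by 3 x 30 and 5 x 30
  c <- grid_spec(15, 300, 30, 10, 10)      # half-pixel shift
  d <- grid_spec(0, 300, 60, 5, 5)         # different pixel size
  e <- grid_spec(0, 300, 30, 10, 10, crs_id = "other")
  expect_true(grids_aligned(a, b))
  expect_false(grids_aligned(a, c))
  expect_false(grids_aligned(a, d))
  expect_false(grids_aligned(a, e))
  expect_equal(unname(grid_extent(a)), c(0, 300, 0, 300))
})

test_that("raster constructors enforce shape, sign and category invariants", {
  g <- make_grid(2, 2)
  expect_error(biomass_raster(matrix(0, 3, 2), g), "3 x 2")
  expect_error(biomass_raster(matrix(-1, 2, 2), g), "non-negative")
  expect_error(biomass_raster(matrix(1, 2, 2), g, nodata = 5), "negative")
  expect_error(forest_mask(matrix(2L, 2, 2), g), "MASK_FOREST")
  expect_error(zone_raster(matrix(-1L, 2, 2), g), ">= 0")
  r <- biomass_raster(matrix(c(0, 10, NA, 30), 2, 2), g)
  expect_identical(sum(is.na(raster_values(r))), 1L)
})

test_that("ESRI ASCII round-trip preserves values, grid and nodata flags", {
  r <- rand_biomass(11, 7, 5, s = 25)
  v <- raster_values(r); v[3, 2] <- NA
  r <- biomass_raster(v, raster_grid(r))
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, path)
  back <- read_raster(path, "biomass")
  expect_true(grids_identical(raster_grid(back), raster_grid(r)))
  expect_identical(raster_values(back), raster_values(r))
  expect_true(is.na(raster_values(back)[3, 2]))
  # the sentinel in the file is -9999 and is flagged on read
  expect_match(readLines(path, n = 6)[6], "NODATA_VALUE -9999")
})

test_that("mask and zone rasters round-trip with their category codes", {
  m <- mk(matrix(c(1L, 0L, NA, 1L), 2, 2))
  pm <- withr::local_tempfile(fileext = ".asc")
  write_raster(m, pm)
  expect_match(paste(readLines(pm), collapse = " "), "255")  # NODATA code
  back <- read_raster(pm, "mask")
  expect_identical(raster_values(back), raster_values(m))

  z <- gen_zones(make_grid(4, 4), 2, 2)
  pz <- withr::local_tempfile(fileext = ".asc")
  write_raster(z, pz)
  expect_identical(raster_values(read_raster(pz, "zones")),
                   raster_values(z))
})

test_that("XLLCENTER headers and malformed files are handled", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCENTER 15", "YLLCENTER 15",
               "CELLSIZE 30", "NODATA_VALUE -9999",
               "1 2", "3 4"), path)
  r <- read_raster(path, "biomass")
  g <- raster_grid(r)
  expect_equal(g$origin_x, 0)
  expect_equal(g$origin_y, 60)

  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "CELLSIZE 30", "1 2 3 4"), bad)
  expect_error(read_raster(bad, "biomass"), "XLLCORNER")
  expect_error(read_raster("nope.asc"), "not found")
  tif <- withr::local_tempfile(fileext = ".tif", lines = "not a grid")
  expect_error(read_raster(tif), "unsupported raster format")
})

test_that("aggregate_mean computes block means with the nodata threshold rule", {
  expect_error(aggregate_mean(bm(matrix(1, 2, 2)), 0), "factor")

  const <- aggregate_mean(bm(matrix(50, 4, 4)), 2)
  expect_equal(raster_values(const), matrix(50, 2, 2))
  expect_equal(raster_grid(const)$pixel_size, 60)

  r <- bm(matrix(c(0, 10, 20, 30), 2, 2, byrow = TRUE))
  expect_equal(raster_values(aggregate_mean(r, 2)), matrix(15, 1, 1))

  holey <- bm(matrix(c(8, NA, NA, NA), 2, 2))
  expect_true(is.na(raster_values(aggregate_mean(holey, 2, 0.5))))
  expect_equal(raster_values(aggregate_mean(holey, 2, 0.25)), matrix(8, 1, 1))
})

test_that("non-divisible factors pad with nodata instead of truncating", {
  r <- bm(matrix(1:9 * 10, 3, 3))
  a <- aggregate_mean(r, 2, min_valid_frac = 0)
  expect_equal(raster_grid(a)$n_rows, 2L)
  expect_equal(raster_grid(a)$n_cols, 2L)
  # corner block holds the single cell [3,3]; mean over its 1 valid cell
  expect_equal(raster_values(a)[2, 2], raster_values(r)[3, 3])
  # totals conserved: sum over cells weighted by valid counts
  expect_equal(sum(raster_values(r)),
               sum(raster_values(aggregate_mean(r, 2, 0)) *
                     c(4, 2, 2, 1)[c(1, 3, 2, 4)]))
})

test_that("aggregation preserves the global mean and composes multiplicatively", {
  for (seed in 1:5) {
    r <- rand_biomass(seed, 12, 12)
    for (f in c(2, 3, 4, 6)) {
      expect_equal(mean(raster_values(aggregate_mean(r, f))),
                   mean(raster_values(r)), tolerance = 1e-12)
    }
    two_step <- aggregate_mean(aggregate_mean(r, 2), 3)
    one_step <- aggregate_mean(r, 6)
    expect_equal(raster_values(two_step), raster_values(one_step),
                 tolerance = 1e-12)
  }
})

test_that("aggregate_mask applies the inclusive forest-fraction threshold", {
  expect_error(aggregate_mask(mk(matrix(0L, 2, 2)), 2, 1.5), "forest_threshold")

  one_in_four <- mk(matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_equal(raster_values(aggregate_mask(one_in_four, 2, 0.20)),
               matrix(MASK_FOREST, 1, 1))
  none <- mk(matrix(0L, 2, 2))
  expect_equal(raster_values(aggregate_mask(none, 2, 0.20)),
               matrix(MASK_NONFOREST, 1, 1))

  # fraction exactly at the threshold counts as forest (1 of 5 valid = 0.20)
  v <- matrix(NA_integer_, 3, 3)
  v[1, 1] <- 1L
  v[c(2, 3), 1] <- 0L; v[1, c(2, 3)] <- 0L
  at_threshold <- mk(v)
  expect_equal(raster_values(aggregate_mask(at_threshold, 3, 0.20)),
               matrix(MASK_FOREST, 1, 1))

  all_na <- forest_mask(matrix(NA_integer_, 2, 2), make_grid(2, 2))
  expect_true(is.na(raster_values(aggregate_mask(all_na, 2))))
})

test_that("raising the forest threshold never creates forest", {
  set.seed(42)
  for (i in 1:20) {
    v <- matrix(sample(c(0L, 1L, NA), 36, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)), 6, 6)
    m <- forest_mask(v, make_grid(6, 6))
    thresholds <- sort(runif(4))
    prev <- NULL
    for (t in thresholds) {
      cur <- raster_values(aggregate_mask(m, 3, t))
      if (!is.null(prev)) {
        gained <- !is.na(cur) & !is.na(prev) &
          cur == MASK_FOREST & prev == MASK_NONFOREST
        expect_false(any(gained))
      }
      prev <- cur
    }
  }
})

test_that("resample_to_grid: identity, factor-2 equivalence, and nearest", {
  r <- rand_biomass(3, 8, 8)
  same <- resample_to_grid(r, raster_grid(r), "area_weighted")
  expect_equal(raster_values(same), raster_values(r))

  agg <- aggregate_mean(r, 2, min_valid_frac = 0)
  rs <- resample_to_grid(r, raster_grid(agg), "area_weighted")
  expect_equal(raster_values(rs), raster_values(agg), tolerance = 1e-12)

  # nearest picks the source cell containing the target center; the
  # center of coarse cell [1,1] is (30, 210), which under the half-open
  # cell convention [x, x+s) x (y-s, y] lies in source cell [2, 2]
  near <- resample_to_grid(r, raster_grid(agg), "nearest")
  v <- raster_values(r)
  expect_equal(raster_values(near)[1, 1], v[2, 2])
  expect_equal(raster_values(near)[2, 2], v[4, 4])

  # fully-nodata source window -> nodata
  hole <- raster_values(r); hole[1:2, 1:2] <- NA
  rh <- biomass_raster(hole, raster_grid(r))
  expect_true(is.na(raster_values(
    resample_to_grid(rh, raster_grid(agg), "area_weighted"))[1, 1]))

  far <- grid_spec(1e6, 1e6, 60, 4, 4)
  expect_error(resample_to_grid(r, far), "disjoint")
  other <- grid_spec(0, 240, 60, 4, 4, crs_id = "utm18n")
  expect_error(resample_to_grid(r, other), "reference systems differ")
  expect_error(resample_to_grid(mk(matrix(0L, 2, 2)), make_grid(1, 1, 60),
                                "area_weighted"), "nearest")
})

test_that("area-weighted regridding matches the brute-force overlap oracle on shifted grids", {
  for (seed in 1:10) {
    r <- rand_biomass(seed + 100, 6, 6, s = 10, na_frac = 0.2)
    set.seed(seed)
    target <- grid_spec(runif(1, -5, 15), 60 - runif(1, -5, 15),
                        runif(1, 8, 35), sample(2:5, 1), sample(2:5, 1))
    got <- raster_values(resample_to_grid(r, target, "area_weighted"))
    want <- oracle_resample_area(r, target)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("common_valid_pairs respects nodata and strata", {
  g <- make_grid(2, 2)
  c_ref <- biomass_raster(matrix(c(10, 20, 0, 5), 2, 2), g)
  m_map <- biomass_raster(matrix(c(5, 20, 0, 10), 2, 2), g)
  p <- common_valid_pairs(c_ref, m_map)
  expect_equal(p$n, 4L)

  holey <- biomass_raster(matrix(c(10, NA, 0, 5), 2, 2), g)
  expect_equal(common_valid_pairs(holey, m_map)$n, 3L)

  mask <- forest_mask(matrix(c(1L, 1L, 0L, 0L), 2, 2), g)
  pf <- common_valid_pairs(c_ref, m_map, mask, "FOREST")
  expect_equal(pf$n, 2L)
  expect_setequal(pf$c, c(10, 20))

  # mask nodata cells drop out of the combined stratum
  mask_na <- forest_mask(matrix(c(1L, NA, 0L, 0L), 2, 2), g)
  expect_equal(common_valid_pairs(c_ref, m_map, mask_na, "ALL")$n, 3L)

  expect_error(common_valid_pairs(c_ref, m_map, stratum = "FOREST"), "mask")
  shifted <- biomass_raster(matrix(1, 2, 2), make_grid(2, 2, ox = 30))
  expect_error(common_valid_pairs(c_ref, shifted), "same grid")
})

test_that("zone aggregation takes the area-majority label with smaller-label ties", {
  z <- zone_raster(matrix(c(1L, 2L, 2L, 1L), 2, 2), make_grid(2, 2))
  a <- aggregate_zones(z, 2)
  expect_equal(raster_values(a), matrix(1L, 1, 1))   # 2-2 tie -> smaller label

  z2 <- zone_raster(matrix(c(2L, 2L, 2L, 1L), 2, 2), make_grid(2, 2))
  expect_equal(raster_values(aggregate_zones(z2, 2)), matrix(2L, 1, 1))

  # zones_to_grid agrees with aggregate_zones on an integer factor
  z3 <- gen_zones(make_grid(8, 8), 2, 4)
  g2 <- raster_grid(aggregate_mean(bm(matrix(1, 8, 8)), 2))
  expect_equal(raster_values(zones_to_grid(z3, g2)),
               raster_values(aggregate_zones(z3, 2)))
})

test_that("mask_to_grid reproduces aggregate_mask on integer-factor targets", {
  set.seed(9)
  v <- matrix(sample(c(0L, 1L, NA), 64, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)), 8, 8)
  m <- forest_mask(v, make_grid(8, 8))
  target <- coarsened <- aggregate_mask(m, 4, 0.2)
  expect_equal(raster_values(mask_to_grid(m, raster_grid(coarsened), 0.2)),
               raster_values(coarsened))
})
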