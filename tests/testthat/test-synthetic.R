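small_cfg <- function(seed = 3, ...) {
  synth_config(grid = grid_spec(0, 48 * 30, 30, 48, 48), seed = seed, ...)
}

test_that("gen_truth is deterministic, bounded and spatially structured", {
  cfg <- small_cfg()
  t1 <- gen_truth(cfg)
  t2 <- gen_truth(cfg)
  expect_identical(raster_values(t1), raster_values(t2))
  expect_false(identical(raster_values(t1),
                         raster_values(gen_truth(small_cfg(seed = 4)))))

  v <- raster_values(t1)
  expect_true(all(v >= 0 & v <= cfg$truth_max))

  # neighbor correlation: high at 150 m correlation length, ~0 at 0
  lag1_cor <- function(m) cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  expect_gt(lag1_cor(v), 0.5)
  v0 <- raster_values(gen_truth(small_cfg(correlation_length = 0)))
  expect_lt(abs(lag1_cor(log(v0))), 0.1)

  # the generator leaves the caller's RNG state untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_truth(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("gen_mask hits the forest fraction and tracks high biomass", {
  cfg <- small_cfg(forest_fraction = 0.5)
  truth <- gen_truth(cfg)
  mask <- gen_mask(truth, cfg)
  n_forest <- sum(raster_values(mask) == MASK_FOREST)
  expect_lte(abs(n_forest - round(0.5 * 48^2)), 1)
  # forest cells carry more biomass than non-forest by construction
  v <- raster_values(truth)
  expect_gt(mean(v[raster_values(mask) == MASK_FOREST]),
            mean(v[raster_values(mask) == MASK_NONFOREST]))

  all_forest <- gen_mask(truth, small_cfg(forest_fraction = 1))
  expect_true(all(raster_values(all_forest) == MASK_FOREST))
  expect_identical(raster_values(mask),
                   raster_values(gen_mask(truth, cfg)))
})

test_that("degrade is the identity when every degradation is switched off", {
  cfg <- small_cfg(gain = 1, offset = 0, noise_sd = 0, ceiling = Inf,
                   zero_outside_forest = FALSE)
  truth <- gen_truth(cfg)
  out <- degrade(truth, NULL, cfg)
  expect_equal(raster_values(out), raster_values(truth))
})

test_that("a pure offset on unclipped cells is recovered by the bias statistic", {
  cfg <- small_cfg(gain = 1, offset = -20, noise_sd = 0, ceiling = Inf,
                   zero_outside_forest = FALSE)
  truth <- gen_truth(cfg)
  out <- degrade(truth, NULL, cfg)
  keep <- raster_values(truth) >= 20
  p <- pair_values(raster_values(truth)[keep], raster_values(out)[keep])
  expect_equal(mbe(p), 20, tolerance = 1e-12)
})

test_that("the saturation ceiling caps the degraded map", {
  cfg <- small_cfg(gain = 1, offset = 0, noise_sd = 0, ceiling = 250,
                   zero_outside_forest = FALSE)
  truth <- gen_truth(cfg)
  expect_gt(max(raster_values(truth)), 250)   # the truth does exceed it
  out <- degrade(truth, NULL, cfg)
  expect_lte(max(raster_values(out)), 250)
})

test_that("affine degradation parameters are recoverable by regression", {
  cfg <- small_cfg(gain = 0.8, offset = 15, noise_sd = 0, ceiling = Inf,
                   zero_outside_forest = FALSE)
  truth <- gen_truth(cfg)
  out <- degrade(truth, NULL, cfg)
  fit <- lm(as.vector(raster_values(out)) ~ as.vector(raster_values(truth)))
  expect_equal(unname(coef(fit)[2]), 0.8, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1]), 15, tolerance = 1e-7)

  noisy_cfg <- synth_config(grid = grid_spec(0, 128 * 30, 30, 128, 128),
                            seed = 11, gain = 0.8, offset = 15,
                            noise_sd = 20, ceiling = Inf,
                            zero_outside_forest = FALSE)
  ntruth <- gen_truth(noisy_cfg)
  nout <- degrade(ntruth, NULL, noisy_cfg)
  keep <- 0.8 * raster_values(ntruth) + 15 > 100   # away from the zero clip
  nfit <- lm(raster_values(nout)[keep] ~ raster_values(ntruth)[keep])
  expect_equal(unname(coef(nfit)[2]), 0.8, tolerance = 0.05)
  expect_equal(unname(coef(nfit)[1]), 15, tolerance = 0.35)
})

test_that("zeroing outside a lagged forest mask leaves the documented signature", {
  cfg <- small_cfg(gain = 1, offset = 0, noise_sd = 0, ceiling = Inf,
                   zero_outside_forest = TRUE, mask_lag_flip_frac = 0)
  truth <- gen_truth(cfg)
  mask <- gen_mask(truth, cfg)
  out <- degrade(truth, mask, cfg)
  nf <- raster_values(mask) == MASK_NONFOREST
  expect_true(all(raster_values(out)[nf] == 0))
  # non-forest stratum: reference higher on average, and a spike at zero
  st <- stratified_pair_stats(truth, out, mask)
  expect_gt(st$mbe[st$stratum == "NONFOREST"], 0)
  h <- biomass_histogram(out, mask, "NONFOREST")
  expect_identical(h$counts[1], sum(nf))   # every non-forest cell tallies at 0

  # a mask time lag leaks biomass across the forest boundary
  lag_cfg <- small_cfg(gain = 1, offset = 0, noise_sd = 0, ceiling = Inf,
                       zero_outside_forest = TRUE, mask_lag_flip_frac = 0.2)
  out_lag <- degrade(truth, mask, lag_cfg)
  expect_gt(sum(raster_values(out_lag)[nf] > 0), 0)
  expect_identical(raster_values(degrade(truth, mask, lag_cfg)),
                   raster_values(out_lag))   # flips are seeded
})

test_that("fni degrades monotonically with the injected noise level", {
  grid <- grid_spec(0, 64 * 30, 30, 64, 64)
  for (seed in 1:5) {
    prev <- Inf
    for (ns in c(0, 20, 60, 150)) {
      cfg <- synth_config(grid = grid, seed = seed, gain = 1, offset = 0,
                          noise_sd = ns, ceiling = Inf,
                          zero_outside_forest = FALSE)
      truth <- gen_truth(cfg)
      out <- degrade(truth, NULL, cfg)
      f <- as.numeric(fni(common_valid_pairs(truth, out)))
      expect_lte(f, prev + 0.02)
      prev <- f
    }
  }
})

test_that("degraded products can live on a coarser native grid", {
  cfg <- small_cfg(native_resolution = 90, noise_sd = 0,
                   zero_outside_forest = FALSE, ceiling = Inf)
  truth <- gen_truth(cfg)
  out <- degrade(truth, NULL, cfg)
  expect_equal(raster_grid(out)$pixel_size, 90)
  expect_equal(raster_grid(out)$n_rows, 16L)
  expect_error(degrade(truth, NULL, small_cfg(native_resolution = 100)),
               "integer multiple")
})

test_that("gen_zones tiles the grid into a complete labelled partition", {
  g <- make_grid(10, 10)
  z <- gen_zones(g, 2, 2)
  v <- raster_values(z)
  expect_setequal(as.vector(v), 1:4)
  expect_true(all(table(v) == 25))       # four 5x5 zones
  expect_equal(raster_values(gen_zones(g, 1, 1)), matrix(1L, 10, 10))
  # non-divisible tilings still label every cell
  z3 <- gen_zones(g, 3, 3)
  expect_false(any(raster_values(z3) == 0))
  expect_setequal(as.vector(raster_values(z3)), 1:9)
  expect_error(gen_zones(g, 0, 2), "positive")
})

test_that("synth_config validates its degradation parameters", {
  expect_error(small_cfg(noise_sd = -1), "noise_sd")
  expect_error(small_cfg(ceiling = 0), "ceiling")
  expect_error(small_cfg(forest_fraction = 1.2), "forest_fraction")
  expect_error(small_cfg(mask_lag_flip_frac = -0.1), "mask_lag_flip_frac")
})
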