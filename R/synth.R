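#' @title Synthetic landscape generator
#' @description
#' Generates matched "high-resolution reference" and "continental
#' product" biomass map pairs with the statistical structure the
#' comparison pipeline assumes, so every stage can be exercised without
#' external rasters. The truth field is a spatially autocorrelated,
#' right-skewed (lognormal-marginal) biomass surface; the forest mask is
#' carved from its upper quantile so that forest correlates with
#' biomass, as in real landscapes; the degraded map applies the
#' discrepancy mechanisms continental products exhibit against lidar
#' references — a gain/offset calibration bias, additive noise, a
#' saturation ceiling (optical/radar predictors lose sensitivity in
#' medium-to-high biomass, so few predictions exceed ~250 Mg ha^-1),
#' zeroed predictions outside a (possibly time-lagged) forest mask, and
#' a coarser native resolution. All stochastic operations take their
#' randomness from the explicit `seed` in the config; the global RNG
#' state is left untouched.
#' @name synthetic_landscape
NULL

# evaluate expr under a local RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic landscape
#'
#' Defaults describe a plausible temperate, partly forested landscape:
#' a lognormal biomass marginal (`meanlog` 4.3, `sdlog` 0.9, i.e. median
#' ~74 Mg ha^-1 with a right tail reaching past 400), spatial
#' correlation length 150 m, 46 % forest, and a degraded product with a
#' 15 % low gain bias, a 10 Mg ha^-1 negative offset, 30 Mg ha^-1
#' additive noise, a 250 Mg ha^-1 saturation ceiling, zeroed
#' predictions outside a forest mask of which 5 % of cells have flipped
#' class (emulating a land-cover time lag).
#'
#' @param grid A [grid_spec()] for the truth field.
#' @param seed Integer seed; identical config + seed gives identical
#'   outputs.
#' @param field_meanlog,field_sdlog Mean and sd of log biomass for the
#'   truth field's marginal distribution.
#' @param correlation_length Spatial correlation length in metres
#'   (Gaussian smoothing scale); 0 gives spatially independent cells.
#' @param forest_fraction Target fraction of cells classed FOREST.
#' @param gain,offset Affine degradation `gain * truth + offset`
#'   (unitless; Mg ha^-1).
#' @param noise_sd Additive Gaussian noise sd, Mg ha^-1 (>= 0).
#' @param ceiling Saturation ceiling, Mg ha^-1 (`Inf` disables).
#' @param native_resolution Native pixel size (m) of the degraded
#'   product; must be a multiple of the truth pixel size. Equal to the
#'   truth pixel size by default (no coarsening).
#' @param zero_outside_forest Zero the degraded map outside the (lagged)
#'   forest mask?
#' @param mask_lag_flip_frac Fraction of mask cells whose class is
#'   flipped before the zeroing, emulating a land-cover time lag.
#' @param truth_max Clip ceiling for the truth field, Mg ha^-1.
#' @return A `synth_config` list.
#' @export
synth_config <- function(grid = grid_spec(0, 256 * 30, 30, 256, 256),
                         seed = 1L,
                         field_meanlog = 4.3, field_sdlog = 0.9,
                         correlation_length = 150,
                         forest_fraction = 0.46,
                         gain = 0.85, offset = -10,
                         noise_sd = 30, ceiling = 250,
                         native_resolution = grid$pixel_size,
                         zero_outside_forest = TRUE,
                         mask_lag_flip_frac = 0.05,
                         truth_max = 450) {
  stopifnot(inherits(grid, "grid_spec"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (ceiling <= 0) stop("`ceiling` must be positive")
  if (forest_fraction < 0 || forest_fraction > 1) {
    stop("`forest_fraction` must be in [0, 1]")
  }
  if (mask_lag_flip_frac < 0 || mask_lag_flip_frac > 1) {
    stop("`mask_lag_flip_frac` must be in [0, 1]")
  }
  if (correlation_length < 0) stop("`correlation_length` must be >= 0")
  f <- native_resolution / grid$pixel_size
  if (f < 1 || abs(f - round(f)) > 1e-9) {
    stop("`native_resolution` must be an integer multiple of the truth pixel size")
  }
  structure(list(grid = grid, seed = as.integer(seed),
                 field_meanlog = field_meanlog, field_sdlog = field_sdlog,
                 correlation_length = correlation_length,
                 forest_fraction = forest_fraction,
                 gain = gain, offset = offset, noise_sd = noise_sd,
                 ceiling = ceiling, native_resolution = native_resolution,
                 zero_outside_forest = zero_outside_forest,
                 mask_lag_flip_frac = mask_lag_flip_frac,
                 truth_max = truth_max),
            class = "synth_config")
}

# separable Gaussian smoothing of a matrix with reflecting edges,
# implemented as banded row/column smoothing matrices
gaussian_smooth <- function(z, sigma) {
  if (sigma <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  smooth_mat <- function(n) {
    s <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- (i - half):(i + half)
      # reflect indices at the edges
      idx <- ifelse(idx < 1L, 2L - idx, idx)
      idx <- ifelse(idx > n, 2L * n - idx, idx)
      for (k in seq_along(idx)) s[i, idx[k]] <- s[i, idx[k]] + kern[k]
    }
    s / rowSums(s)
  }
  sr <- smooth_mat(nrow(z))
  sc <- smooth_mat(ncol(z))
  sr %*% z %*% t(sc)
}

#' Generate the synthetic truth biomass field
#'
#' Seeded white noise is smoothed with a separable Gaussian kernel at
#' the configured correlation length, re-standardized, mapped through
#' `exp(meanlog + sdlog * z)` to a right-skewed lognormal-marginal
#' biomass surface, and clipped to `[0, truth_max]`.
#'
#' @param config A [synth_config()].
#' @return A [biomass_raster()] on `config$grid`.
#' @export
gen_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$grid
  z <- with_seed(config$seed,
                 matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols))
  sigma <- config$correlation_length / g$pixel_size
  z <- gaussian_smooth(z, sigma)
  z <- (z - mean(z)) / stats::sd(z)
  vals <- exp(config$field_meanlog + config$field_sdlog * z)
  vals <- pmin(pmax(vals, 0), config$truth_max)
  biomass_raster(vals, g)
}

#' Derive a forest mask from the truth field
#'
#' The highest-biomass cells are classed FOREST until the target forest
#' fraction is met (ties toward forest), so the mask is correlated with
#' biomass by construction. The realized forest-cell count is within one
#' cell of `round(forest_fraction * n_cells)`.
#'
#' @param truth A [biomass_raster()] from [gen_truth()].
#' @param config A [synth_config()].
#' @return A [forest_mask()] on the same grid.
#' @export
gen_mask <- function(truth, config) {
  stopifnot(inherits(truth, "biomass_raster"), inherits(config, "synth_config"))
  v <- truth$values
  n <- length(v)
  k <- round(config$forest_fraction * n)
  out <- matrix(MASK_NONFOREST, nrow(v), ncol(v))
  if (k > 0L) {
    ord <- order(v, decreasing = TRUE)   # ties resolved by position: toward forest
    out[ord[seq_len(k)]] <- MASK_FOREST
  }
  forest_mask(out, truth$grid)
}

#' Degrade the truth field into a synthetic continental product
#'
#' Applies, in order: the affine calibration bias
#' `gain * truth + offset`, additive Gaussian noise, clipping at zero,
#' the saturation ceiling, zeroing outside the lag-perturbed forest mask
#' (a seeded `mask_lag_flip_frac` of mask cells have their class
#' flipped first), and finally block-mean aggregation to the product's
#' native resolution.
#'
#' @param truth A [biomass_raster()].
#' @param mask The [forest_mask()] for the landscape (used only when
#'   `config$zero_outside_forest` is `TRUE`).
#' @param config A [synth_config()].
#' @return A [biomass_raster()] at `config$native_resolution`.
#' @export
degrade <- function(truth, mask, config) {
  stopifnot(inherits(truth, "biomass_raster"), inherits(config, "synth_config"))
  g <- truth$grid
  vals <- config$gain * truth$values + config$offset
  if (config$noise_sd > 0) {
    eps <- with_seed(config$seed + 1L,
                     matrix(stats::rnorm(length(vals), sd = config$noise_sd),
                            nrow(vals), ncol(vals)))
    vals <- vals + eps
  }
  vals <- pmin(pmax(vals, 0), config$ceiling)
  if (isTRUE(config$zero_outside_forest)) {
    stopifnot(inherits(mask, "forest_mask"))
    check_same_grid(truth, mask, "truth and mask")
    mv <- mask$values
    if (config$mask_lag_flip_frac > 0) {
      n_flip <- round(config$mask_lag_flip_frac * length(mv))
      if (n_flip > 0L) {
        flip <- with_seed(config$seed + 2L,
                          sample.int(length(mv), n_flip))
        mv[flip] <- ifelse(is.na(mv[flip]), NA,
                           ifelse(mv[flip] == MASK_FOREST,
                                  MASK_NONFOREST, MASK_FOREST))
      }
    }
    vals[is.na(mv) | mv == MASK_NONFOREST] <- 0
  }
  out <- biomass_raster(vals, g)
  if (config$native_resolution != g$pixel_size) {
    f <- config$native_resolution / g$pixel_size
    if (abs(f - round(f)) > 1e-9) {
      stop("`native_resolution` must be an integer multiple of the truth pixel size")
    }
    out <- aggregate_mean(out, round(f), min_valid_frac = 0)
  }
  out
}

#' Rectangular zone tiling
#'
#' Partitions a grid into `n_rows_z x n_cols_z` rectangular zones
#' labelled `1..n_rows_z * n_cols_z` in row-major order — a stand-in
#' for county polygons. When the zone counts do not divide the grid,
#' edge zones absorb the remainder cells, so the labels always
#' partition the whole grid.
#'
#' @param grid A [grid_spec()].
#' @param n_rows_z,n_cols_z Positive integer zone counts along rows and
#'   columns.
#' @return A [zone_raster()].
#' @export
gen_zones <- function(grid, n_rows_z, n_cols_z) {
  stopifnot(inherits(grid, "grid_spec"))
  n_rows_z <- as.integer(n_rows_z); n_cols_z <- as.integer(n_cols_z)
  if (is.na(n_rows_z) || is.na(n_cols_z) || n_rows_z < 1L || n_cols_z < 1L) {
    stop("zone counts must be positive integers")
  }
  if (n_rows_z > grid$n_rows || n_cols_z > grid$n_cols) {
    stop("more zones than grid cells along an axis")
  }
  zr <- pmin(ceiling(seq_len(grid$n_rows) / (grid$n_rows / n_rows_z)), n_rows_z)
  zc <- pmin(ceiling(seq_len(grid$n_cols) / (grid$n_cols / n_cols_z)), n_cols_z)
  vals <- outer(zr, zc, function(i, j) (i - 1L) * n_cols_z + j)
  zone_raster(vals, grid)
}
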