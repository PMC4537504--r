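# Small fixture builders and independent oracles shared across tests.

make_grid <- function(nr, nc, s = 30, ox = 0, oy = nr * s, crs = "local") {
  grid_spec(ox, oy, s, nr, nc, crs_id = crs)
}

# biomass raster from a matrix given row-by-row (byrow, as you read it)
bm <- function(m, s = 30, ox = 0, oy = NULL) {
  m <- as.matrix(m)
  if (is.null(oy)) oy <- nrow(m) * s
  biomass_raster(m, grid_spec(ox, oy, s, nrow(m), ncol(m)))
}

mk <- function(m, s = 30) {
  m <- as.matrix(m)
  forest_mask(m, grid_spec(0, nrow(m) * s, s, nrow(m), ncol(m)))
}

# seeded random biomass raster, optionally with nodata holes
rand_biomass <- function(seed, nr, nc, s = 30, na_frac = 0) {
  set.seed(seed)
  v <- matrix(runif(nr * nc, 0, 400), nr, nc)
  if (na_frac > 0) v[runif(nr * nc) < na_frac] <- NA
  biomass_raster(v, grid_spec(0, nr * s, s, nr, nc))
}

# Brute-force area-weighted regridding oracle: explicit rectangle
# intersection of every (target cell, source cell) pair. Deliberately
# independent of the package's separable-matrix implementation.
oracle_resample_area <- function(r, target, min_valid_frac = 0) {
  g <- raster_grid(r)
  v <- raster_values(r)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  ts <- target$pixel_size; ss <- g$pixel_size
  for (ti in seq_len(target$n_rows)) {
    for (tj in seq_len(target$n_cols)) {
      tx0 <- target$origin_x + (tj - 1) * ts; tx1 <- tx0 + ts
      ty1 <- target$origin_y - (ti - 1) * ts; ty0 <- ty1 - ts
      wsum <- 0; vsum <- 0; wtot <- 0
      for (si in seq_len(g$n_rows)) {
        for (sj in seq_len(g$n_cols)) {
          sx0 <- g$origin_x + (sj - 1) * ss; sx1 <- sx0 + ss
          sy1 <- g$origin_y - (si - 1) * ss; sy0 <- sy1 - ss
          a <- max(0, min(tx1, sx1) - max(tx0, sx0)) *
               max(0, min(ty1, sy1) - max(ty0, sy0))
          if (a <= 0) next
          wtot <- wtot + a
          if (!is.na(v[si, sj])) {
            wsum <- wsum + a
            vsum <- vsum + a * v[si, sj]
          }
        }
      }
      if (wtot > 0 && wsum > 0 && wsum >= min_valid_frac * wtot) {
        out[ti, tj] <- vsum / wsum
      }
    }
  }
  out
}
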