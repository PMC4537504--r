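#' @title Regridding between arbitrary aligned-CRS grids
#' @description
#' `resample_to_grid()` moves a raster onto any target grid in the same
#' reference system. The `area_weighted` method computes, for each
#' target cell, the mean of the valid source cells weighted by their
#' geometric overlap area with the target cell — the natural choice for
#' a density variable like biomass (Mg ha^-1), because it conserves
#' totals over shared extents. Because grids are axis-aligned, the 2-D
#' overlap areas factor into a product of 1-D interval overlaps along x
#' and y, which keeps the computation a pair of small matrix products.
#' `nearest` takes the value of the source cell containing each target
#' cell centre and is the only method meaningful for categorical rasters.
#' @name regridding
NULL

# 1-D overlap-length matrix between target intervals and source
# intervals. Edges are positions along an increasing axis.
overlap_weights <- function(target_edges, source_edges) {
  nt <- length(target_edges) - 1L
  ns <- length(source_edges) - 1L
  w <- matrix(0, nt, ns)
  for (k in seq_len(nt)) {
    lo <- target_edges[k]; hi <- target_edges[k + 1L]
    j0 <- max(1L, findInterval(lo, source_edges))
    if (j0 > ns) next
    for (j in j0:ns) {
      if (source_edges[j] >= hi) break
      ov <- min(hi, source_edges[j + 1L]) - max(lo, source_edges[j])
      if (ov > 0) w[k, j] <- ov
    }
  }
  w
}

#' Resample a raster onto a target grid
#'
#' @param r A `value_raster` (any subclass).
#' @param target A [grid_spec()] with the same `crs_id` as `r` and an
#'   extent overlapping `r`'s.
#' @param method `"area_weighted"` (overlap-area-weighted mean of valid
#'   source cells; default) or `"nearest"` (source cell containing the
#'   target cell centre). Categorical rasters (masks, zones) must use
#'   `"nearest"`.
#' @param min_valid_frac For `area_weighted`: minimum fraction of a
#'   target cell's source-covered area that must be valid, else nodata.
#'   The default 0 keeps any cell with some valid overlap. Target cells
#'   entirely outside the source extent are always nodata.
#' @return A raster of the same class on `target`.
#' @export
resample_to_grid <- function(r, target, method = c("area_weighted", "nearest"),
                             min_valid_frac = 0) {
  stopifnot(inherits(r, "value_raster"), inherits(target, "grid_spec"))
  method <- match.arg(method)
  g <- r$grid
  if (!identical(g$crs_id, target$crs_id)) {
    stop(sprintf("reference systems differ ('%s' vs '%s'); reprojection is not supported",
                 g$crs_id, target$crs_id))
  }
  es <- grid_extent(g); et <- grid_extent(target)
  if (et["xmin"] >= es["xmax"] || et["xmax"] <= es["xmin"] ||
      et["ymin"] >= es["ymax"] || et["ymax"] <= es["ymin"]) {
    stop("target extent is disjoint from the source extent")
  }
  categorical <- inherits(r, c("forest_mask", "zone_raster"))
  if (categorical && method != "nearest") {
    stop("categorical rasters (masks, zones) must be resampled with method = \"nearest\"")
  }
  out <- if (method == "nearest") {
    resample_nearest(r$values, g, target)
  } else {
    resample_area_weighted(r$values, g, target, min_valid_frac)
  }
  new_value_raster(out, target, r$nodata, setdiff(class(r), "value_raster"))
}

resample_nearest <- function(vals, g, target) {
  xc <- grid_cell_centers_x(target)
  yc <- grid_cell_centers_y(target)
  cols <- floor((xc - g$origin_x) / g$pixel_size) + 1
  rows <- floor((g$origin_y - yc) / g$pixel_size) + 1
  cols[cols < 1 | cols > g$n_cols] <- NA
  rows[rows < 1 | rows > g$n_rows] <- NA
  out <- matrix(vals[1][NA], target$n_rows, target$n_cols)
  storage.mode(out) <- storage.mode(vals)
  ok <- outer(!is.na(rows), !is.na(cols), `&`)
  idx <- cbind(rep(rows, times = target$n_cols), rep(cols, each = target$n_rows))
  out[ok] <- vals[idx[as.vector(ok), , drop = FALSE]]
  out
}

resample_area_weighted <- function(vals, g, target, min_valid_frac) {
  # x axis increases with column; y handled on a "depth below top" axis
  sx <- g$origin_x + (0:g$n_cols) * g$pixel_size
  tx <- target$origin_x + (0:target$n_cols) * target$pixel_size
  sy <- -(g$origin_y - (0:g$n_rows) * g$pixel_size)
  ty <- -(target$origin_y - (0:target$n_rows) * target$pixel_size)
  wx <- overlap_weights(tx, sx)            # n_tcols x n_scols
  wy <- overlap_weights(ty, sy)            # n_trows x n_srows
  valid <- !is.na(vals)
  v0 <- vals; v0[!valid] <- 0
  num <- wy %*% v0 %*% t(wx)               # sum of value * overlap area
  wvalid <- wy %*% (valid + 0) %*% t(wx)   # valid overlap area
  wtotal <- wy %*% matrix(1, g$n_rows, g$n_cols) %*% t(wx)
  out <- num / wvalid                      # 0/0 -> NaN where no valid overlap
  out[wvalid == 0 | wtotal == 0] <- NA
  if (min_valid_frac > 0) out[wvalid < min_valid_frac * wtotal] <- NA
  out
}

#' Bring a forest mask onto an arbitrary coarser grid
#'
#' Generalizes [aggregate_mask()] to targets that are not integer
#' multiples of the source grid: the forest indicator is resampled by
#' overlap-area weighting, giving each target cell its forest-area
#' fraction, which is then thresholded (inclusively). For aligned
#' integer-factor targets the result is identical to [aggregate_mask()].
#'
#' @param m A [forest_mask()].
#' @param target A [grid_spec()].
#' @param forest_threshold Forest-fraction threshold in `[0, 1]`.
#' @return A [forest_mask()] on `target`.
#' @export
mask_to_grid <- function(m, target, forest_threshold = 0.20) {
  stopifnot(inherits(m, "forest_mask"))
  indicator <- value_raster((m$values == MASK_FOREST) + 0, m$grid)
  frac <- resample_to_grid(indicator, target, "area_weighted")$values
  out <- matrix(MASK_NONFOREST, target$n_rows, target$n_cols)
  out[frac >= forest_threshold] <- MASK_FOREST
  out[is.na(frac)] <- NA
  forest_mask(out, target)
}

#' Bring a zone raster onto an arbitrary coarser grid
#'
#' Each target cell takes the zone label covering the largest share of
#' its area (area-majority); ties break toward the smaller label. Cells
#' with no zone coverage become 0.
#'
#' @param z A [zone_raster()].
#' @param target A [grid_spec()].
#' @return A [zone_raster()] on `target`.
#' @export
zones_to_grid <- function(z, target) {
  stopifnot(inherits(z, "zone_raster"))
  labels <- sort(unique(as.vector(z$values)))
  labels <- labels[!is.na(labels)]
  best_area <- matrix(0, target$n_rows, target$n_cols)
  out <- matrix(0L, target$n_rows, target$n_cols)
  for (lab in labels) {
    ind <- value_raster((z$values == lab) + 0, z$grid)
    a <- resample_to_grid(ind, target, "area_weighted")$values
    a[is.na(a)] <- 0
    # strict > keeps the smaller (earlier) label on ties
    take <- a > best_area
    out[take] <- lab
    best_area[take] <- a[take]
  }
  zone_raster(out, target)
}
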