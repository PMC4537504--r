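#' @title Resolution-ladder convergence analysis
#' @description
#' Map agreement is re-evaluated along a ladder of coarsening target
#' resolutions (default 250 m, 500 m, 1 km, 4 km). Both maps are brought
#' to a shared grid at each rung by overlap-area-weighted regridding;
#' cell-level statistics trace the "mean biomass density" agreement
#' curve, and, when a zone raster is supplied, per-zone totals trace the
#' "total biomass" curve. Random, uncorrelated disagreement between two
#' maps averages out under coarsening (RMSD falls roughly with the
#' square root of the number of cells merged), while a shared additive
#' bias survives every rung unchanged — which is why a convergence curve
#' separates noise-like from systematic discrepancies.
#' @name scale_convergence
NULL

#' Default resolution ladder (m)
#' @export
DEFAULT_LADDER <- c(250, 500, 1000, 4000)

#' Bring a map pair to each rung of a resolution ladder
#'
#' @param c_ref,m_map [biomass_raster()]s sharing a `crs_id` (native
#'   resolutions may differ).
#' @param resolutions Increasing target resolutions in metres; each must
#'   be at least as coarse as both native resolutions.
#' @param method Regridding method (see [resample_to_grid()]).
#' @param min_valid_frac Passed to [resample_to_grid()].
#' @return A `resolution_ladder`: list of rungs, each a list with
#'   `resolution`, `c_ref`, `m_map` on a shared [grid_spec()] anchored
#'   at the reference map's origin.
#' @export
resolution_ladder <- function(c_ref, m_map, resolutions = DEFAULT_LADDER,
                              method = "area_weighted", min_valid_frac = 0) {
  stopifnot(inherits(c_ref, "value_raster"), inherits(m_map, "value_raster"))
  if (length(resolutions) == 0L) stop("`resolutions` must be nonempty")
  if (is.unsorted(resolutions, strictly = TRUE)) {
    stop("`resolutions` must be strictly increasing")
  }
  native <- max(c_ref$grid$pixel_size, m_map$grid$pixel_size)
  if (any(resolutions < native)) {
    stop(sprintf(
      "requested resolution finer than a native input (%g m); coarsest native is the floor",
      native))
  }
  g <- c_ref$grid
  rungs <- lapply(resolutions, function(res) {
    target <- grid_spec(g$origin_x, g$origin_y, res,
                        ceiling(g$n_rows * g$pixel_size / res),
                        ceiling(g$n_cols * g$pixel_size / res),
                        crs_id = g$crs_id)
    list(resolution = res,
         c_ref = if (grids_identical(target, c_ref$grid)) c_ref else
           resample_to_grid(c_ref, target, method, min_valid_frac),
         m_map = if (grids_identical(target, m_map$grid)) m_map else
           resample_to_grid(m_map, target, method, min_valid_frac))
  })
  structure(rungs, class = "resolution_ladder")
}

#' Agreement statistics along a resolution ladder
#'
#' @param ladder A [resolution_ladder()].
#' @param mask Optional [forest_mask()] at its native resolution; it is
#'   re-thresholded onto each rung's grid (see [mask_to_grid()]).
#' @param zones Optional [zone_raster()] at its native resolution,
#'   regridded to each rung by area-majority label; when supplied the
#'   per-zone mean-density and total-biomass comparison statistics are
#'   added.
#' @param stratum Stratum for the cell-level statistics.
#' @param forest_threshold Forest-fraction threshold used when
#'   regridding `mask`.
#' @param both_zero_term Passed to [fni()].
#' @return A data.frame, one row per rung: `resolution`, `n_cells`,
#'   `r2_mean`, `rmsd_mean`, `mbe_mean`, `fni_mean` (cell-level, on
#'   densities) and, with zones, `n_zones`, `r2_zmean`, `rmsd_zmean`,
#'   `r2_total`, `rmsd_total`, `mbe_total`. Statistics undefined at a
#'   rung (e.g. an empty stratum) are `NA`.
#' @export
convergence_curve <- function(ladder, mask = NULL, zones = NULL,
                              stratum = "ALL", forest_threshold = 0.20,
                              both_zero_term = 1.0) {
  stopifnot(inherits(ladder, "resolution_ladder"))
  rows <- lapply(ladder, function(rung) {
    g <- rung$c_ref$grid
    rmask <- if (!is.null(mask)) mask_to_grid(mask, g, forest_threshold)
    ps <- pair_stats(common_valid_pairs(rung$c_ref, rung$m_map, rmask, stratum),
                     stratum = stratum, resolution = rung$resolution,
                     both_zero_term = both_zero_term)
    row <- data.frame(resolution = rung$resolution, n_cells = ps$n,
                      r2_mean = ps$r2, rmsd_mean = ps$rmsd,
                      mbe_mean = ps$mbe, fni_mean = ps$fni)
    if (!is.null(zones)) {
      rz <- zones_to_grid(zones, g)
      za <- zonal_summaries(rung$c_ref, rz, rmask, stratum, map_id = "C")
      zb <- zonal_summaries(rung$m_map, rz, rmask, stratum, map_id = "M")
      cm <- compare_zonal(za, zb, "mean")
      ct <- compare_zonal(za, zb, "total")
      row$n_zones <- cm$n_zones
      row$r2_zmean <- cm$r2
      row$rmsd_zmean <- rmsd(pair_values(cm$zones$a, cm$zones$b))
      row$r2_total <- ct$r2
      row$rmsd_total <- rmsd(pair_values(ct$zones$a, ct$zones$b))
      row$mbe_total <- ct$mbe
    }
    row
  })
  do.call(rbind, rows)
}

#' First resolution at which a curve stays converged
#'
#' Scans a convergence curve (sorted by increasing resolution) for the
#' first rung from which the cell-level RMSD is at and remains at or
#' below `epsilon` through the coarsest rung.
#'
#' @param curve A data.frame from [convergence_curve()] (needs columns
#'   `resolution` and `rmsd_mean`), sorted by resolution.
#' @param epsilon RMSD threshold in Mg ha^-1. There is no canonical
#'   value for "near-perfect" agreement; the default 5 Mg ha^-1 is an
#'   arbitrary, documented choice.
#' @return The resolution (m) of the first sustained crossing, or `NA`
#'   if the curve never stays below `epsilon`.
#' @examples
#' curve <- data.frame(resolution = c(250, 500, 1000, 4000, 10000),
#'                     rmsd_mean = c(80, 50, 30, 10, 9))
#' convergence_scale(curve, epsilon = 15)  # 4000
#' @export
convergence_scale <- function(curve, epsilon = 5) {
  if (is.null(curve) || nrow(curve) == 0L) stop("empty convergence curve")
  if (is.unsorted(curve$resolution, strictly = TRUE)) {
    stop("`curve` must be sorted by strictly increasing resolution")
  }
  suffix_max <- rev(cummax(rev(curve$rmsd_mean)))
  hit <- which(suffix_max <= epsilon)
  if (length(hit) == 0L) NA_real_ else curve$resolution[hit[1L]]
}
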