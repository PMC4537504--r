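#' @title Zonal and state-level biomass accounting
#' @description
#' Aggregates per-cell biomass density (Mg ha^-1) into per-zone mean
#' density and total standing biomass. Units: a cell of edge `s` metres
#' has area `s^2` m^2 = `s^2 / 1e4` ha = `s^2 / 1e6` km^2; total biomass
#' is reported in teragrams (1 Tg = 1e6 Mg), so
#' `total (Tg) = mean density (Mg/ha) x area (km^2) x 100 (ha/km^2) x 1e-6 (Tg/Mg)`.
#' Areas are *compared areas*: valid-cell count times pixel area, not
#' nominal polygon area, so maps with coverage gaps are accounted on the
#' cells they actually predict.
#' @name zonal_accounting
NULL

#' Convert a mean biomass density and an area to a total
#'
#' @param mean_density Mean aboveground biomass density, Mg ha^-1 (>= 0).
#' @param area_km2 Area in km^2 (>= 0).
#' @return Total biomass in Tg.
#' @examples
#' total_from_mean(100, 100)  # 1 Tg
#' @export
total_from_mean <- function(mean_density, area_km2) {
  if (any(mean_density < 0, na.rm = TRUE) || any(area_km2 < 0, na.rm = TRUE)) {
    stop("mean density and area must be non-negative")
  }
  mean_density * area_km2 * 100 * 1e-6
}

zonal_one <- function(vals, keep, zone_id, map_id, stratum, pixel_size) {
  v <- vals[keep]
  n <- length(v)
  area_km2 <- n * pixel_size^2 / 1e6
  if (n == 0L) {
    mean_d <- NA_real_; total <- NA_real_
  } else {
    mean_d <- mean(v)
    total <- sum(v) * pixel_size^2 / 1e4 * 1e-6   # Mg/ha * ha -> Mg -> Tg
  }
  data.frame(zone_id = zone_id, map_id = map_id, stratum = stratum,
             n_cells = n, area_km2 = area_km2, mean_density = mean_d,
             total_biomass_tg = total, resolution = pixel_size)
}

stratum_keep <- function(r, mask, stratum) {
  keep <- !is.na(r$values)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "forest_mask"))
    check_same_grid(r, mask, "raster and mask")
    keep <- keep & switch(stratum,
                          ALL = !is.na(mask$values),
                          FOREST = !is.na(mask$values) & mask$values == MASK_FOREST,
                          NONFOREST = !is.na(mask$values) & mask$values == MASK_NONFOREST)
  } else if (stratum != "ALL") {
    stop(sprintf("stratum \"%s\" requested but no forest mask supplied", stratum))
  }
  keep
}

#' Per-zone biomass summaries
#'
#' For every zone label present in `zones` (label 0 = outside all zones
#' is skipped), reports the valid-cell count, the compared area, the
#' mean density over valid stratum cells and the total biomass. A zone
#' with no valid stratum cell keeps its row with `n_cells = 0` and `NA`
#' mean/total, so coverage gaps stay visible.
#'
#' @param r A [biomass_raster()].
#' @param zones A [zone_raster()] on the same grid.
#' @param mask Optional [forest_mask()]; required for non-`ALL` strata.
#' @param stratum `"ALL"`, `"FOREST"` or `"NONFOREST"`.
#' @param map_id Label recorded in the `map_id` column.
#' @return A data.frame, one row per zone: `zone_id`, `map_id`,
#'   `stratum`, `n_cells`, `area_km2`, `mean_density` (Mg ha^-1),
#'   `total_biomass_tg` (Tg), `resolution` (m).
#' @export
zonal_summaries <- function(r, zones, mask = NULL,
                            stratum = c("ALL", "FOREST", "NONFOREST"),
                            map_id = "map") {
  stopifnot(inherits(r, "value_raster"), inherits(zones, "zone_raster"))
  stratum <- match.arg(stratum)
  check_same_grid(r, zones, "raster and zones")
  keep <- stratum_keep(r, mask, stratum)
  labels <- sort(unique(as.vector(zones$values)))
  labels <- labels[!is.na(labels) & labels > 0L]
  if (length(labels) == 0L) stop("zone raster contains no zones (all labels 0)")
  rows <- lapply(labels, function(lab) {
    zonal_one(r$values, keep & !is.na(zones$values) & zones$values == lab,
              lab, map_id, stratum, r$grid$pixel_size)
  })
  do.call(rbind, rows)
}

#' Whole-map totals by forest class
#'
#' The state-level accounting: one summary row per stratum (FOREST,
#' NONFOREST, ALL) over the full raster extent. With a gap-free mask the
#' forest and non-forest totals add up to the combined total.
#'
#' @param r A [biomass_raster()].
#' @param mask A [forest_mask()] on the same grid.
#' @param map_id Label recorded in the rows.
#' @return A data.frame with rows FOREST, NONFOREST, ALL (columns as
#'   [zonal_summaries()], `zone_id = 1`).
#' @export
state_totals <- function(r, mask, map_id = "map") {
  stopifnot(inherits(r, "value_raster"), inherits(mask, "forest_mask"))
  check_same_grid(r, mask, "raster and mask")
  rows <- lapply(c("FOREST", "NONFOREST", "ALL"), function(s) {
    zonal_one(r$values, stratum_keep(r, mask, s), 1L, map_id, s,
              r$grid$pixel_size)
  })
  do.call(rbind, rows)
}

#' Compare two maps' zonal summaries
#'
#' Pairs two zonal-summary tables on their common zone set (the sets
#' must match) and compares the chosen quantity: an ordinary
#' least-squares fit of map `b` on map `a`, the 1:1-line coefficient of
#' determination with `a` as the reference `C`, and the mean bias error
#' `mean(a - b)`.
#'
#' @param a,b Data.frames from [zonal_summaries()], for the reference
#'   map and the comparison map respectively.
#' @param on `"mean"` (per-zone mean density, Mg ha^-1) or `"total"`
#'   (per-zone total biomass, Tg).
#' @return A `zonal_comparison`: list with `on`, `n_zones`, `slope`,
#'   `intercept` (`NA` when fewer than 2 zones), `r2`, `mbe`, and the
#'   paired table `zones` (`zone_id`, `a`, `b`).
#' @export
compare_zonal <- function(a, b, on = c("mean", "total")) {
  on <- match.arg(on)
  col <- if (on == "mean") "mean_density" else "total_biomass_tg"
  if (!setequal(a$zone_id, b$zone_id)) {
    stop("zone sets differ between the two summaries")
  }
  b <- b[match(a$zone_id, b$zone_id), ]
  keep <- !is.na(a[[col]]) & !is.na(b[[col]])
  x <- a[[col]][keep]
  y <- b[[col]][keep]
  n <- length(x)
  if (n < 1L) stop("no zones with valid summaries in both maps")
  if (n >= 2L && stats::var(x) > 0) {
    fit <- stats::lm.fit(cbind(1, x), y)
    intercept <- fit$coefficients[[1]]
    slope <- fit$coefficients[[2]]
  } else {
    intercept <- NA_real_; slope <- NA_real_
  }
  p <- pair_values(x, y)
  r2 <- if (n >= 2L && sum((y - mean(y))^2) > 0) r_squared(p) else NA_real_
  structure(list(on = on, n_zones = n, slope = slope, intercept = intercept,
                 r2 = r2, mbe = mbe(p),
                 zones = data.frame(zone_id = a$zone_id[keep], a = x, b = y)),
            class = "zonal_comparison")
}

#' @export
print.zonal_comparison <- function(x, ...) {
  cat(sprintf(
    "<zonal_comparison> on %s: %d zones, slope %.3f, intercept %.3f, R2 %.3f, MBE (C - M) %.3f\n",
    x$on, x$n_zones, x$slope, x$intercept, x$r2, x$mbe))
  invisible(x)
}
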