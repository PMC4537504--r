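#' @title Raster containers
#' @description
#' Three thin S3 containers hold gridded data on a [grid_spec()]:
#' `biomass_raster` for aboveground biomass density (Mg ha^-1, values
#' must be non-negative), `forest_mask` for the ternary
#' forest/non-forest/nodata stratification raster, and `zone_raster`
#' for integer zone labels (counties, regions; label 0 means "outside
#' all zones"). Missing cells are held as `NA` internally; the numeric
#' `nodata` sentinel is only used on file I/O. A fourth, more permissive
#' container, `value_raster`, carries derived per-cell quantities that
#' may be negative (difference maps) or unitless (similarity maps).
#'
#' Mask category codes used on file I/O: FOREST = 1, NONFOREST = 0,
#' NODATA = 255.
#' @name rasters
NULL

#' Mask category codes
#'
#' Integer codes used for forest masks in files and in the `values`
#' matrix of a [forest_mask()]: `MASK_FOREST = 1`, `MASK_NONFOREST = 0`;
#' nodata cells are `NA` in memory and 255 in files.
#' @export
MASK_FOREST <- 1L

#' @rdname MASK_FOREST
#' @export
MASK_NONFOREST <- 0L

#' @rdname MASK_FOREST
#' @export
MASK_NODATA_CODE <- 255L

#' Default numeric nodata sentinel written to files
#' @export
DEFAULT_NODATA <- -9999

new_value_raster <- function(values, grid, nodata, class) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop(sprintf("values are %d x %d but the grid is %d x %d",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  }
  structure(list(grid = grid, values = values, nodata = nodata),
            class = c(class, "value_raster"))
}

#' General-purpose value raster
#'
#' Holds any numeric per-cell quantity (e.g. a signed difference map or a
#' 0-1 similarity map) on a grid. Unlike [biomass_raster()] no sign
#' constraint is imposed.
#'
#' @param values Numeric matrix (`NA` = nodata), dimensions matching `grid`.
#' @param grid A [grid_spec()].
#' @param nodata Numeric sentinel substituted for `NA` when the raster is
#'   written to a file.
#' @return A `value_raster`.
#' @export
value_raster <- function(values, grid, nodata = DEFAULT_NODATA) {
  storage.mode(values) <- "double"
  new_value_raster(values, grid, nodata, character(0))
}

#' Biomass density raster
#'
#' @param values Numeric matrix of biomass density in Mg ha^-1
#'   (`NA` = nodata). All non-missing values must be >= 0; the nodata
#'   sentinel must not itself be a legal biomass value.
#' @inheritParams value_raster
#' @return A `biomass_raster` (also a `value_raster`).
#' @examples
#' g <- grid_spec(0, 60, 30, 2, 2)
#' r <- biomass_raster(matrix(c(0, 10, 20, 30), 2, 2), g)
#' raster_values(r)
#' @export
biomass_raster <- function(values, grid, nodata = DEFAULT_NODATA) {
  storage.mode(values) <- "double"
  if (any(values < 0, na.rm = TRUE)) {
    stop("biomass density values must be non-negative (Mg ha^-1); ",
         "use NA for nodata cells")
  }
  if (nodata >= 0) {
    stop("`nodata` sentinel must be negative so it can never be a legal ",
         "biomass value")
  }
  new_value_raster(values, grid, nodata, "biomass_raster")
}

#' Ternary forest mask raster
#'
#' @param values Integer matrix over `{MASK_FOREST, MASK_NONFOREST, NA}`.
#' @param grid A [grid_spec()].
#' @return A `forest_mask`.
#' @export
forest_mask <- function(values, grid) {
  storage.mode(values) <- "integer"
  bad <- !(values %in% c(MASK_FOREST, MASK_NONFOREST)) & !is.na(values)
  if (any(bad)) {
    stop("mask values must be MASK_FOREST (1), MASK_NONFOREST (0) or NA")
  }
  new_value_raster(values, grid, MASK_NODATA_CODE, "forest_mask")
}

#' Integer zone-label raster
#'
#' Zones stand in for county/state polygons: each cell carries a
#' non-negative integer label, with 0 meaning "outside all zones".
#'
#' @param values Integer matrix of non-negative labels (`NA` treated as
#'   outside all zones).
#' @param grid A [grid_spec()].
#' @return A `zone_raster`.
#' @export
zone_raster <- function(values, grid) {
  storage.mode(values) <- "integer"
  if (any(values < 0L, na.rm = TRUE)) stop("zone labels must be >= 0")
  new_value_raster(values, grid, -1L, "zone_raster")
}

#' Extract the value matrix / grid of a raster
#' @param r A `value_raster` (or subclass).
#' @return `raster_values()`: the values matrix (`NA` = nodata);
#'   `raster_grid()`: the [grid_spec()].
#' @export
raster_values <- function(r) {
  stopifnot(inherits(r, "value_raster"))
  r$values
}

#' @rdname raster_values
#' @export
raster_grid <- function(r) {
  stopifnot(inherits(r, "value_raster"))
  r$grid
}

#' @export
print.value_raster <- function(x, ...) {
  kind <- class(x)[1L]
  v <- x$values
  nv <- sum(!is.na(v))
  cat(sprintf("<%s> %s, %d/%d valid cells", kind, format(x$grid),
              nv, length(v)))
  if (nv > 0L && !inherits(x, c("forest_mask", "zone_raster"))) {
    cat(sprintf(", range [%g, %g]", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

# shared precondition for cell-wise binary operations
check_same_grid <- function(a, b, what = "rasters") {
  if (!grids_identical(a$grid, b$grid)) {
    stop(sprintf(
      "%s are not on the same grid (%s vs %s); regrid first",
      what, format(a$grid), format(b$grid)))
  }
  invisible(TRUE)
}
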