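#' Planar raster grid specification
#'
#' A `grid_spec` describes the georeferenced grid a raster lives on: the
#' planar coordinate of the top-left corner, the (square) pixel edge length
#' in metres, the array dimensions, and an opaque label for the shared
#' coordinate reference system. Cell `(row, col)` covers the half-open
#' square `[x, x + s) x (y - s, y]` where `x = origin_x + (col - 1) * s`
#' and `y = origin_y - (row - 1) * s`: rows run downward from the top edge,
#' the convention used by most gridded land-cover products.
#'
#' @param origin_x,origin_y Planar coordinates (m) of the top-left corner
#'   of the grid (the upper-left corner of cell `[1, 1]`).
#' @param pixel_size Cell edge length in metres; cells are square, so the
#'   pixel area is `pixel_size^2` m^2.
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param crs_id Opaque label for the planar reference system. Rasters can
#'   only be combined when their `crs_id` matches; no reprojection is
#'   performed by this package.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 3000, pixel_size = 30, n_rows = 100, n_cols = 100)
#' grid_extent(g)
#' @export
grid_spec <- function(origin_x, origin_y, pixel_size, n_rows, n_cols,
                      crs_id = "local") {
  stopifnot(is.numeric(origin_x), length(origin_x) == 1L, is.finite(origin_x),
            is.numeric(origin_y), length(origin_y) == 1L, is.finite(origin_y))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (metres)")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("`n_rows` and `n_cols` must be positive integers")
  }
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size),
         n_rows = n_rows, n_cols = n_cols,
         crs_id = as.character(crs_id)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells @ %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_id))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm", x$n_rows, x$n_cols, x$pixel_size)
}

#' Spatial extent of a grid
#'
#' @param g A [grid_spec()].
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
grid_extent <- function(g) {
  stopifnot(inherits(g, "grid_spec"))
  c(xmin = g$origin_x,
    xmax = g$origin_x + g$n_cols * g$pixel_size,
    ymin = g$origin_y - g$n_rows * g$pixel_size,
    ymax = g$origin_y)
}

#' Test whether two grids are aligned
#'
#' Two grids are aligned when they share the reference system and pixel
#' size and their origins differ by integer multiples of the pixel size,
#' so that cell boundaries coincide wherever the grids overlap.
#'
#' @param a,b [grid_spec()] objects.
#' @param tol Relative tolerance on the origin-offset integrality check.
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  if (!identical(a$crs_id, b$crs_id)) return(FALSE)
  if (abs(a$pixel_size - b$pixel_size) > tol * a$pixel_size) return(FALSE)
  dx <- (a$origin_x - b$origin_x) / a$pixel_size
  dy <- (a$origin_y - b$origin_y) / a$pixel_size
  abs(dx - round(dx)) <= tol && abs(dy - round(dy)) <= tol
}

#' Test whether two grids are identical
#'
#' @param a,b [grid_spec()] objects.
#' @param tol Absolute tolerance on origins and pixel size (m).
#' @return `TRUE` or `FALSE`.
#' @export
grids_identical <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  identical(a$crs_id, b$crs_id) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol
}

# coarsened grid after block aggregation by integer factor (pad rule:
# dims round up, never truncate)
coarsen_grid <- function(g, factor) {
  grid_spec(g$origin_x, g$origin_y, g$pixel_size * factor,
            ceiling(g$n_rows / factor), ceiling(g$n_cols / factor),
            crs_id = g$crs_id)
}

# x/y coordinates of cell centers
grid_cell_centers_x <- function(g) g$origin_x + (seq_len(g$n_cols) - 0.5) * g$pixel_size
grid_cell_centers_y <- function(g) g$origin_y - (seq_len(g$n_rows) - 0.5) * g$pixel_size
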