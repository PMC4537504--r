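#' @title Raster file I/O
#' @description
#' Rasters are stored as single-band **ESRI ASCII grids** (`.asc` or
#' `.txt`): the plain-text `NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/`
#' `NODATA_VALUE` header followed by rows of values, top row first.
#' `XLLCENTER`/`YLLCENTER` headers are accepted and converted to corner
#' registration. The format is text-based, self-describing and read by
#' every mainstream GIS, which keeps the pipeline free of binary
#' dependencies.
#'
#' Masks are written as integer rasters with FOREST = 1, NONFOREST = 0,
#' NODATA = 255; zones as their integer labels with nodata -1.
#' @name raster_io
NULL

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt")) return("asc")
  stop(sprintf(
    "unsupported raster format '.%s' for '%s': rasters are read and written as ESRI ASCII grids (.asc/.txt); convert GeoTIFFs with e.g. `gdal_translate -of AAIGrid`",
    ext, path))
}

#' Read a single-band raster file
#'
#' @param path Path to an ESRI ASCII grid (`.asc`/`.txt`).
#' @param kind One of `"biomass"`, `"mask"`, `"zones"`, `"values"`;
#'   selects the returned container and its validation.
#' @param crs_id Reference-system label to attach (the format stores
#'   none); rasters can only be combined when labels match.
#' @param nodata Optional sentinel overriding the file's `NODATA_VALUE`.
#' @return A [biomass_raster()], [forest_mask()], [zone_raster()] or
#'   [value_raster()] according to `kind`.
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, kind = c("biomass", "mask", "zones", "values"),
                        crs_id = "local", nodata = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  parsed <- switch(file_format(path), asc = read_asc_file(path))
  vals <- parsed$values
  nd <- if (!is.null(nodata)) nodata else parsed$nodata
  if (!is.null(nd)) vals[!is.na(vals) & vals == nd] <- NA
  g <- grid_spec(parsed$origin_x, parsed$origin_y, parsed$pixel_size,
                 nrow(vals), ncol(vals), crs_id = crs_id)
  switch(kind,
         biomass = biomass_raster(vals, g,
                                  nodata = if (!is.null(nd) && nd < 0) nd else DEFAULT_NODATA),
         mask = {
           vals[!is.na(vals) & vals == MASK_NODATA_CODE] <- NA
           forest_mask(vals, g)
         },
         zones = zone_raster(vals, g),
         values = value_raster(vals, g))
}

#' Write a raster to disk
#'
#' @param r A `value_raster` (or subclass).
#' @param path Output path (`.asc`/`.txt`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "value_raster"))
  vals <- r$values
  nd <- if (inherits(r, "forest_mask")) MASK_NODATA_CODE else r$nodata
  vals[is.na(vals)] <- nd
  switch(file_format(path), asc = write_asc_file(vals, r$grid, nd, path))
  invisible(path)
}

read_asc_file <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  n_header <- 0L
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop(sprintf("'%s': no data rows found", path))
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2L && is.na(suppressWarnings(as.numeric(tok[1])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      n_header <- n_header + 1L
      if (n_header > 8L) stop(sprintf("'%s': malformed ASCII grid header", path))
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing) > 0L) {
    stop(sprintf("'%s': ASCII grid header lacks %s", path,
                 paste(toupper(missing), collapse = ", ")))
  }
  s <- hdr$cellsize
  if (s <= 0) stop(sprintf("'%s': CELLSIZE must be positive", path))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner
  } else if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - s / 2
  } else stop(sprintf("'%s': header lacks XLLCORNER/XLLCENTER", path))
  if (!is.null(hdr$yllcorner)) {
    yll <- hdr$yllcorner
  } else if (!is.null(hdr$yllcenter)) {
    yll <- hdr$yllcenter - s / 2
  } else stop(sprintf("'%s': header lacks YLLCORNER/YLLCENTER", path))
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("'%s': expected %d values (%d x %d), found %d",
                 path, nr * nc, nr, nc, length(vals)))
  }
  list(values = matrix(vals, nrow = nr, ncol = nc, byrow = TRUE),
       origin_x = xll, origin_y = yll + nr * s, pixel_size = s,
       nodata = hdr$nodata_value)
}

write_asc_file <- function(vals, g, nodata, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", g$n_cols),
    sprintf("NROWS %d", g$n_rows),
    sprintf("XLLCORNER %.10g", g$origin_x),
    sprintf("YLLCORNER %.10g", g$origin_y - g$n_rows * g$pixel_size),
    sprintf("CELLSIZE %.10g", g$pixel_size),
    sprintf("NODATA_VALUE %.10g", nodata)
  ), con)
  utils::write.table(format(vals, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
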