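#' @title Block aggregation
#' @description
#' Coarsening by an integer factor `f` replaces each `f x f` block of
#' input cells with one output cell. Biomass rasters take the arithmetic
#' mean of the valid cells in the block (so the block mean is an unbiased
#' density for the block area and totals are conserved); forest masks are
#' re-classified by the fraction of valid cells that are forest, against
#' a threshold (20 % by default, matching the "more than 20 percent tree
#' dominance" forest definition used by NLCD-style land-cover products);
#' zone rasters take the most frequent label. When `f` does not divide
#' the grid dimensions the raster is padded right/bottom with nodata
#' cells rather than truncated, so no data are discarded.
#' @name aggregation
NULL

# pad a matrix with NA on the right/bottom to multiples of f
pad_to_factor <- function(vals, f) {
  nr <- ceiling(nrow(vals) / f) * f
  nc <- ceiling(ncol(vals) / f) * f
  if (nr == nrow(vals) && nc == ncol(vals)) return(vals)
  out <- matrix(vals[1][NA], nr, nc)
  storage.mode(out) <- storage.mode(vals)
  out[seq_len(nrow(vals)), seq_len(ncol(vals))] <- vals
  out
}

# sum of each f x f block (NAs must be handled by the caller)
block_sum <- function(x, f) {
  gr <- rep(seq_len(nrow(x) / f), each = f)
  gc <- rep(seq_len(ncol(x) / f), each = f)
  out <- t(rowsum(t(rowsum(x, gr, reorder = FALSE)), gc, reorder = FALSE))
  dimnames(out) <- NULL
  out
}

check_factor <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 1 || factor != round(factor)) {
    stop("`factor` must be a single integer >= 1")
  }
  as.integer(factor)
}

#' Aggregate a biomass raster by block mean
#'
#' Each output cell is the arithmetic mean of the valid input cells in
#' its `factor x factor` block. Blocks whose valid-cell fraction (out of
#' `factor^2`, counting padding as invalid) falls below `min_valid_frac`
#' become nodata.
#'
#' @param r A [biomass_raster()] (any `value_raster` is accepted).
#' @param factor Positive integer aggregation factor; the output pixel
#'   size is `factor` times the input pixel size. Non-divisible
#'   dimensions are padded with nodata, never truncated.
#' @param min_valid_frac Minimum fraction of valid cells per block, in
#'   `[0, 1]`; below it the output cell is nodata. Blocks with no valid
#'   cell are always nodata.
#' @return A raster of the same class on the coarsened grid.
#' @examples
#' g <- grid_spec(0, 60, 30, 2, 2)
#' r <- biomass_raster(matrix(c(0, 20, 10, 30), 2, 2), g)
#' raster_values(aggregate_mean(r, 2))  # 15
#' @export
aggregate_mean <- function(r, factor, min_valid_frac = 0.5) {
  stopifnot(inherits(r, "value_raster"))
  f <- check_factor(factor)
  if (!is.numeric(min_valid_frac) || min_valid_frac < 0 || min_valid_frac > 1) {
    stop("`min_valid_frac` must be in [0, 1]")
  }
  if (f == 1L) return(r)
  vals <- pad_to_factor(r$values, f)
  valid <- !is.na(vals)
  vals[!valid] <- 0
  n_valid <- block_sum(valid + 0, f)
  means <- block_sum(vals, f) / n_valid    # 0/0 -> NaN for empty blocks
  means[n_valid == 0 | n_valid / f^2 < min_valid_frac] <- NA
  new_value_raster(means, coarsen_grid(r$grid, f), r$nodata,
                   setdiff(class(r), "value_raster"))
}

#' Aggregate a forest mask by forest-fraction threshold
#'
#' An output cell is FOREST when the fraction of its block's valid cells
#' that are forest is at least `forest_threshold` (the comparison is
#' inclusive, so a block at exactly the threshold is forest), NODATA when
#' the block has no valid cells, and NONFOREST otherwise.
#'
#' @param m A [forest_mask()].
#' @param factor Positive integer aggregation factor (pad rule as
#'   [aggregate_mean()]).
#' @param forest_threshold Forest-fraction threshold in `[0, 1]`;
#'   default 0.20.
#' @return A [forest_mask()] on the coarsened grid.
#' @export
aggregate_mask <- function(m, factor, forest_threshold = 0.20) {
  stopifnot(inherits(m, "forest_mask"))
  f <- check_factor(factor)
  if (!is.numeric(forest_threshold) || length(forest_threshold) != 1L ||
      is.na(forest_threshold) || forest_threshold < 0 || forest_threshold > 1) {
    stop("`forest_threshold` must be a single number in [0, 1]")
  }
  if (f == 1L) return(m)
  vals <- pad_to_factor(m$values, f)
  valid <- !is.na(vals)
  forest <- !is.na(vals) & vals == MASK_FOREST
  n_valid <- block_sum(valid + 0, f)
  n_forest <- block_sum(forest + 0, f)
  frac <- n_forest / n_valid
  out <- matrix(MASK_NONFOREST, nrow(frac), ncol(frac))
  out[frac >= forest_threshold] <- MASK_FOREST
  out[n_valid == 0] <- NA
  forest_mask(out, coarsen_grid(m$grid, f))
}

#' Aggregate a zone raster by majority label
#'
#' Each output cell takes the most frequent label among its block's
#' cells (padding and `NA` cells are ignored); ties are broken toward
#' the smaller label so the result is deterministic. Blocks with no
#' labelled cells become 0 (outside all zones).
#'
#' @param z A [zone_raster()].
#' @param factor Positive integer aggregation factor.
#' @return A [zone_raster()] on the coarsened grid.
#' @export
aggregate_zones <- function(z, factor) {
  stopifnot(inherits(z, "zone_raster"))
  f <- check_factor(factor)
  if (f == 1L) return(z)
  vals <- pad_to_factor(z$values, f)
  nr_out <- nrow(vals) / f
  nc_out <- ncol(vals) / f
  out <- matrix(0L, nr_out, nc_out)
  for (i in seq_len(nr_out)) {
    rows <- ((i - 1L) * f + 1L):(i * f)
    for (j in seq_len(nc_out)) {
      block <- vals[rows, ((j - 1L) * f + 1L):(j * f)]
      block <- block[!is.na(block)]
      if (length(block) == 0L) next
      tab <- table(block)
      # which.max returns the first maximum; table names are sorted
      # numerically ascending, so ties go to the smaller label
      out[i, j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  zone_raster(out, coarsen_grid(z$grid, f))
}
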