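#' @title Pairwise map-comparison statistics
#' @description
#' The five statistics used to compare a reference biomass map `C`
#' against a second map `M` over `n` paired cells:
#'
#' \deqn{R^2 = 1 - \frac{\sum_i (C_i - M_i)^2}{\sum_i (M_i - \bar M)^2}}
#' \deqn{RMSD = \sqrt{\sum_i (C_i - M_i)^2 / n}}
#' \deqn{RMSD\% = 100 \cdot RMSD / \bar C}
#' \deqn{MBE = \sum_i (C_i - M_i) / n}
#' \deqn{FNI = \frac{1}{n}\sum_i \left(1 - \frac{|C_i - M_i|}{\max(C_i, M_i)}\right)}
#'
#' `R^2` here is a coefficient of determination about the 1:1 line, not
#' a squared correlation: it can be negative when the maps disagree more
#' than `M` varies about its own mean, and it is asymmetric (`M` is the
#' reference in the denominator), as is `RMSD%` (normalized by the mean
#' of `C`). `MBE > 0` means the reference map is higher on average. The
#' Fuzzy Numerical Index (FNI) is a per-cell relative similarity in
#' `[0, 1]` (0 = fully distinct, 1 = fully identical), defined for
#' non-negative values; a cell with `C = M = 0` is perfectly similar and
#' contributes `both_zero_term` (default 1).
#' @name map_statistics
NULL

#' Coefficient of determination about the 1:1 line
#'
#' @param pairs A `pair_values` object (see [common_valid_pairs()]).
#' @return Unitless scalar, at most 1, possibly negative.
#' @examples
#' r_squared(pair_values(c(1, 2, 3), c(1, 2, 4)))
#' @export
r_squared <- function(pairs) {
  p <- as_pair_values(pairs)
  if (p$n < 2L) stop("r_squared() needs at least 2 pairs")
  denom <- sum((p$m - mean(p$m))^2)
  if (denom == 0) {
    stop("r_squared() is undefined when the comparison map M is constant")
  }
  1 - sum((p$c - p$m)^2) / denom
}

#' Root-mean-square difference (Mg ha^-1)
#'
#' @inheritParams r_squared
#' @return Non-negative scalar in the units of the inputs.
#' @export
rmsd <- function(pairs) {
  p <- as_pair_values(pairs)
  if (p$n < 1L) stop("rmsd() needs at least 1 pair")
  sqrt(sum((p$c - p$m)^2) / p$n)
}

#' RMSD as a percentage of the reference-map mean
#'
#' @inheritParams r_squared
#' @return Percentage (`100 * rmsd / mean(C)`).
#' @export
rmsd_pct <- function(pairs) {
  p <- as_pair_values(pairs)
  cbar <- mean(p$c)
  if (cbar == 0) {
    stop("rmsd_pct() is undefined when the reference mean is zero")
  }
  100 * rmsd(p) / cbar
}

#' Mean bias error (Mg ha^-1)
#'
#' Signed mean of `C - M`: positive when the reference map `C` is higher
#' on average.
#'
#' @inheritParams r_squared
#' @return Signed scalar in the units of the inputs.
#' @export
mbe <- function(pairs) {
  p <- as_pair_values(pairs)
  if (p$n < 1L) stop("mbe() needs at least 1 pair")
  mean(p$c - p$m)
}

# per-cell FNI terms; x, y non-negative, equal length, no NAs
fni_terms <- function(x, y, both_zero_term) {
  mx <- pmax(x, y)
  out <- 1 - abs(x - y) / mx
  out[mx == 0] <- both_zero_term
  out
}

#' Fuzzy Numerical Index
#'
#' Mean per-cell relative similarity `1 - |C - M| / max(C, M)`, in
#' `[0, 1]`. Requires non-negative inputs. The `0/0` cell (both maps
#' zero) is undefined by the formula; two identical zeros are treated as
#' fully similar and contribute `both_zero_term` (default 1). The count
#' of such cells is attached as attribute `n_both_zero`.
#'
#' @inheritParams r_squared
#' @param both_zero_term Similarity assigned to cells where both maps
#'   are exactly zero.
#' @return Scalar in `[0, 1]` (when `both_zero_term` is), with attribute
#'   `n_both_zero`.
#' @examples
#' fni(pair_values(c(10, 0), c(5, 0)))  # mean of 0.5 and 1
#' @export
fni <- function(pairs, both_zero_term = 1.0) {
  p <- as_pair_values(pairs)
  if (p$n < 1L) stop("fni() needs at least 1 pair")
  if (any(p$c < 0) || any(p$m < 0)) {
    stop("fni() is defined for non-negative values only")
  }
  terms <- fni_terms(p$c, p$m, both_zero_term)
  structure(mean(terms), n_both_zero = sum(p$c == 0 & p$m == 0))
}

#' Per-cell Fuzzy Numerical Index map
#'
#' The spatial counterpart of [fni()]: each cell of the result carries
#' `1 - |C - M| / max(C, M)`; nodata in either input propagates. The
#' mean of the valid cells equals `fni()` on the corresponding pairs.
#'
#' @param c_ref,m_map [biomass_raster()]s on the same grid.
#' @param both_zero_term Similarity assigned to both-zero cells.
#' @return A [value_raster()] of similarities in `[0, 1]`.
#' @export
fni_map <- function(c_ref, m_map, both_zero_term = 1.0) {
  stopifnot(inherits(c_ref, "value_raster"), inherits(m_map, "value_raster"))
  check_same_grid(c_ref, m_map)
  if (any(c_ref$values < 0, na.rm = TRUE) || any(m_map$values < 0, na.rm = TRUE)) {
    stop("fni_map() is defined for non-negative values only")
  }
  keep <- !is.na(c_ref$values) & !is.na(m_map$values)
  out <- matrix(NA_real_, c_ref$grid$n_rows, c_ref$grid$n_cols)
  out[keep] <- fni_terms(c_ref$values[keep], m_map$values[keep], both_zero_term)
  value_raster(out, c_ref$grid)
}

#' Signed difference map (reference minus comparison)
#'
#' @param c_ref,m_map Rasters on the same grid.
#' @return A [value_raster()] of `C - M`; nodata propagates.
#' @export
difference_map <- function(c_ref, m_map) {
  stopifnot(inherits(c_ref, "value_raster"), inherits(m_map, "value_raster"))
  check_same_grid(c_ref, m_map)
  value_raster(c_ref$values - m_map$values, c_ref$grid)
}

#' Biomass histogram in fixed-width bins
#'
#' Counts valid stratum cells into half-open, left-inclusive bins
#' `[k*w, (k+1)*w)` over `range` (default 10 Mg ha^-1 bins over
#' 0-400 Mg ha^-1, the convention of biomass-distribution plots).
#' Values at or above the range top are tallied in a separate overflow
#' bin. Exact zeros can be excluded (`include_zeros = FALSE`) to focus
#' the distribution on predicted-biomass cells.
#'
#' @param r A [biomass_raster()].
#' @param mask,stratum As in [common_valid_pairs()].
#' @param include_zeros Count cells with value exactly 0?
#' @param bin_width Bin width (Mg ha^-1).
#' @param range Length-2 numeric, the tallied range (left edge of the
#'   first bin, right edge of the last).
#' @return A `biomass_histogram`: list with `bin_left`, `bin_right`,
#'   `counts`, `overflow` (count above the range), `n` (total tallied,
#'   including overflow), `include_zeros`, `stratum`.
#' @export
biomass_histogram <- function(r, mask = NULL,
                              stratum = c("ALL", "FOREST", "NONFOREST"),
                              include_zeros = TRUE,
                              bin_width = 10, range = c(0, 400)) {
  stopifnot(inherits(r, "value_raster"))
  stratum <- match.arg(stratum)
  if (bin_width <= 0) stop("`bin_width` must be positive")
  if (length(range) != 2L || range[2] <= range[1]) {
    stop("`range` must be c(lo, hi) with hi > lo")
  }
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
  v <- r$values[keep]
  if (!include_zeros) v <- v[v != 0]
  if (any(v < range[1])) {
    stop("values below the histogram range; extend `range`")
  }
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  n_bins <- length(edges) - 1L
  idx <- findInterval(v, edges)            # left-inclusive, half-open
  counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
  structure(list(bin_left = edges[-length(edges)],
                 bin_right = edges[-1],
                 counts = counts,
                 overflow = sum(idx > n_bins),
                 n = length(v),
                 include_zeros = include_zeros,
                 stratum = stratum),
            class = "biomass_histogram")
}

#' @export
print.biomass_histogram <- function(x, ...) {
  cat(sprintf("<biomass_histogram> %d cells (%s%s), %d bins of %g, overflow %d\n",
              x$n, x$stratum, if (x$include_zeros) "" else ", zeros excluded",
              length(x$counts), x$bin_right[1] - x$bin_left[1], x$overflow))
  invisible(x)
}

#' @export
as.data.frame.biomass_histogram <- function(x, ...) {
  data.frame(bin_left = c(x$bin_left, x$bin_right[length(x$bin_right)]),
             bin_right = c(x$bin_right, Inf),
             count = c(x$counts, x$overflow))
}

#' Full statistics for one map pair on one stratum
#'
#' @inheritParams r_squared
#' @param stratum,resolution Labels recorded in the output row.
#' @param both_zero_term Passed to [fni()].
#' @return One-row data.frame: `stratum`, `resolution`, `n`, `r2`,
#'   `rmsd`, `rmsd_pct`, `mbe`, `fni`, `n_both_zero`. Statistics that
#'   are undefined for the pairs at hand (fewer than 2 pairs or a
#'   constant `M` for `r2`; a zero reference mean for `rmsd_pct`) are
#'   `NA` rather than an error, so degenerate strata stay visible in
#'   report tables.
#' @export
pair_stats <- function(pairs, stratum = "ALL", resolution = NA_real_,
                       both_zero_term = 1.0) {
  p <- as_pair_values(pairs)
  if (p$n == 0L) {
    return(data.frame(stratum = stratum, resolution = resolution, n = 0L,
                      r2 = NA_real_, rmsd = NA_real_, rmsd_pct = NA_real_,
                      mbe = NA_real_, fni = NA_real_, n_both_zero = NA_integer_))
  }
  r2 <- if (p$n >= 2L && sum((p$m - mean(p$m))^2) > 0) r_squared(p) else NA_real_
  rp <- if (mean(p$c) != 0) rmsd_pct(p) else NA_real_
  f <- fni(p, both_zero_term)
  data.frame(stratum = stratum, resolution = resolution, n = p$n,
             r2 = r2, rmsd = rmsd(p), rmsd_pct = rp, mbe = mbe(p),
             fni = as.numeric(f), n_both_zero = attr(f, "n_both_zero"))
}

#' Statistics for one map pair over all three strata
#'
#' Computes [pair_stats()] for the combined, forest-only and
#' non-forest-only strata of a map pair. Empty strata yield a row with
#' `n = 0` and `NA` statistics.
#'
#' @param c_ref,m_map [biomass_raster()]s on one grid.
#' @param mask A [forest_mask()] on the same grid, or `NULL` (then only
#'   the `ALL` stratum is computed).
#' @param resolution Resolution label (m) recorded in the rows; defaults
#'   to the grid pixel size.
#' @param both_zero_term Passed to [fni()].
#' @return A data.frame with one row per stratum.
#' @export
stratified_pair_stats <- function(c_ref, m_map, mask = NULL,
                                  resolution = NULL, both_zero_term = 1.0) {
  if (is.null(resolution)) resolution <- c_ref$grid$pixel_size
  strata <- if (is.null(mask)) "ALL" else c("ALL", "FOREST", "NONFOREST")
  rows <- lapply(strata, function(s) {
    pair_stats(common_valid_pairs(c_ref, m_map, mask, s),
               stratum = s, resolution = resolution,
               both_zero_term = both_zero_term)
  })
  do.call(rbind, rows)
}
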