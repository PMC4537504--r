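#' Paired cell values from two co-registered maps
#'
#' Extracts the `(C_i, M_i)` value pairs used by all the comparison
#' statistics: cells that are valid (non-nodata) in both rasters and
#' that fall in the requested stratum of the forest mask. By convention
#' `C` is the reference map (the high-resolution product the comparison
#' is anchored on) and `M` the map under evaluation; several statistics
#' are asymmetric in the two roles.
#'
#' @param c_ref Reference [biomass_raster()] (the `C` of the statistics).
#' @param m_map Comparison [biomass_raster()] (the `M`).
#' @param mask Optional [forest_mask()] on the same grid; required when
#'   `stratum` is not `"ALL"`. When a mask is supplied, `"ALL"` means
#'   forest and non-forest combined: cells where the mask itself is
#'   nodata are excluded.
#' @param stratum `"ALL"`, `"FOREST"` or `"NONFOREST"`.
#' @return A `pair_values` object: list with numeric vectors `c` and `m`
#'   and the pair count `n`.
#' @export
common_valid_pairs <- function(c_ref, m_map, mask = NULL,
                               stratum = c("ALL", "FOREST", "NONFOREST")) {
  stopifnot(inherits(c_ref, "value_raster"), inherits(m_map, "value_raster"))
  stratum <- match.arg(stratum)
  check_same_grid(c_ref, m_map)
  keep <- !is.na(c_ref$values) & !is.na(m_map$values)
  if (is.null(mask)) {
    if (stratum != "ALL") {
      stop(sprintf("stratum \"%s\" requested but no forest mask supplied", stratum))
    }
  } else {
    stopifnot(inherits(mask, "forest_mask"))
    check_same_grid(c_ref, mask, "raster and mask")
    keep <- keep & switch(stratum,
                          ALL = !is.na(mask$values),
                          FOREST = !is.na(mask$values) & mask$values == MASK_FOREST,
                          NONFOREST = !is.na(mask$values) & mask$values == MASK_NONFOREST)
  }
  pair_values(c_ref$values[keep], m_map$values[keep])
}

#' Construct paired values directly from two vectors
#'
#' @param c_vals,m_vals Equal-length numeric vectors of reference (`C`)
#'   and comparison (`M`) values; no missing values allowed.
#' @return A `pair_values` object.
#' @export
pair_values <- function(c_vals, m_vals) {
  if (length(c_vals) != length(m_vals)) {
    stop("paired vectors must have equal length")
  }
  if (anyNA(c_vals) || anyNA(m_vals)) {
    stop("pair_values() does not accept missing values; filter them first")
  }
  structure(list(c = as.numeric(c_vals), m = as.numeric(m_vals),
                 n = length(c_vals)),
            class = "pair_values")
}

#' @export
print.pair_values <- function(x, ...) {
  cat(sprintf("<pair_values> n = %d\n", x$n))
  invisible(x)
}

as_pair_values <- function(pairs) {
  if (inherits(pairs, "pair_values")) return(pairs)
  stop("`pairs` must be a pair_values object (see common_valid_pairs())")
}
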