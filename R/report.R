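#' @title Pipeline runs and report bundles
#' @description
#' `run_synth()` materializes a synthetic landscape (truth, degraded
#' product, mask, zones) as ESRI ASCII rasters plus a key-value manifest
#' of every generating parameter, and `run_compare()` executes the full
#' pixel-to-zone-to-state comparison workflow for a set of maps against
#' a designated reference, writing CSV tables, difference/FNI rasters
#' and a plain-text log. The reference map (the `C` of the asymmetric
#' statistics) is always explicit in the configuration, never inferred.
#' Every threshold, seed and silent data decision (nodata exclusions,
#' both-zero FNI cells) is recorded in the log so each reported number
#' can be recomputed from the written intermediates.
#' @name pipeline_runs
NULL

#' Comparison run configuration
#'
#' @param maps Named list of [biomass_raster()]s **or** named character
#'   vector/list of file paths; names are the map labels (unique).
#' @param reference Label of the reference map (the `C` of the
#'   statistics).
#' @param mask A [forest_mask()] or path, or `NULL`.
#' @param zones A [zone_raster()] or path, or `NULL`.
#' @param strata Strata to compute (subset of ALL/FOREST/NONFOREST;
#'   non-ALL strata require a mask).
#' @param ladder Resolution ladder in metres (see [resolution_ladder()]).
#' @param forest_threshold,min_valid_frac,epsilon Pipeline thresholds:
#'   forest-fraction threshold for mask regridding, minimum valid
#'   fraction for block means, and the convergence RMSD threshold
#'   (Mg ha^-1).
#' @param hist_bin_width,hist_range,hist_include_zeros Histogram
#'   settings (see [biomass_histogram()]).
#' @param out_dir Output directory for the report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(maps, reference, mask = NULL, zones = NULL,
                       strata = c("ALL", "FOREST", "NONFOREST"),
                       ladder = DEFAULT_LADDER,
                       forest_threshold = 0.20, min_valid_frac = 0.5,
                       epsilon = 5,
                       hist_bin_width = 10, hist_range = c(0, 400),
                       hist_include_zeros = TRUE,
                       out_dir = "agbcompare_out") {
  if (is.null(names(maps)) || anyDuplicated(names(maps)) ||
      any(!nzchar(names(maps)))) {
    stop("`maps` must be a named collection with unique, nonempty labels")
  }
  if (!reference %in% names(maps)) {
    stop(sprintf("reference label '%s' is not among the map labels", reference))
  }
  if (length(maps) < 2L) stop("need at least 2 maps (a reference and one comparison)")
  strata <- match.arg(strata, several.ok = TRUE)
  if (is.null(mask) && any(strata != "ALL")) {
    stop("FOREST/NONFOREST strata requested but no mask configured")
  }
  structure(list(maps = maps, reference = reference, mask = mask,
                 zones = zones, strata = strata, ladder = ladder,
                 forest_threshold = forest_threshold,
                 min_valid_frac = min_valid_frac, epsilon = epsilon,
                 hist_bin_width = hist_bin_width, hist_range = hist_range,
                 hist_include_zeros = hist_include_zeros,
                 out_dir = out_dir),
            class = "run_config")
}

load_map <- function(x, kind) {
  if (inherits(x, "value_raster")) return(x)
  read_raster(x, kind)
}

#' Run the full map-comparison workflow
#'
#' For every non-reference map, against the reference: stratified pair
#' statistics at native comparison resolution, difference and FNI
#' rasters, histograms, zonal summaries and zonal comparisons (when
#' zones are configured), state totals by forest class, and the
#' resolution-ladder convergence curve with its convergence scale.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the assembled tables (`pair_stats`,
#'   `state_totals`, `zonal`, `zonal_comparisons`, `convergence`,
#'   `convergence_scale`) and `out_dir`. Files written: `pair_stats.csv`,
#'   `state_totals.csv`, `zonal_summaries.csv`, `zonal_comparison.csv`,
#'   `convergence.csv`, `histogram_<label>_<stratum>.csv`,
#'   `diff_<label>.asc`, `fni_<label>.asc`, `run_log.txt`.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("agbcompare comparison run  [%s]",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("reference map (C of all statistics): %s", config$reference),
                 sprintf("MBE sign convention: C - M (positive = reference higher)"),
                 sprintf("forest_threshold = %g (inclusive)", config$forest_threshold),
                 sprintf("min_valid_frac = %g", config$min_valid_frac),
                 sprintf("convergence epsilon = %g Mg/ha", config$epsilon),
                 sprintf("ladder = %s m", paste(config$ladder, collapse = ", ")))

  maps <- lapply(config$maps, load_map, kind = "biomass")
  mask <- if (!is.null(config$mask)) load_map(config$mask, "mask")
  zones <- if (!is.null(config$zones)) load_map(config$zones, "zones")
  ref <- maps[[config$reference]]
  others <- maps[names(maps) != config$reference]

  all_stats <- list(); all_state <- list(); all_zonal <- list()
  all_zcmp <- list(); all_curves <- list(); conv_scales <- list()

  # reference-map histograms and state totals once
  if (!is.null(mask)) {
    mask_ref <- if (grids_identical(mask$grid, ref$grid)) mask else
      mask_to_grid(mask, ref$grid, config$forest_threshold)
    all_state[[config$reference]] <-
      state_totals(ref, mask_ref, map_id = config$reference)
  }
  write_histograms <- function(r, label, msk) {
    for (s in config$strata) {
      h <- biomass_histogram(r, msk, s,
                             include_zeros = config$hist_include_zeros,
                             bin_width = config$hist_bin_width,
                             range = config$hist_range)
      utils::write.csv(as.data.frame(h),
                       file.path(config$out_dir,
                                 sprintf("histogram_%s_%s.csv", label, s)),
                       row.names = FALSE)
    }
  }
  if (!is.null(mask)) write_histograms(ref, config$reference, mask_ref)

  for (label in names(others)) {
    m <- others[[label]]
    # bring the pair onto a shared comparison grid: the coarser of the two
    if (!grids_identical(ref$grid, m$grid)) {
      if (!identical(ref$grid$crs_id, m$grid$crs_id)) {
        stop(sprintf("map '%s' is in crs '%s' but the reference is in '%s'",
                     label, m$grid$crs_id, ref$grid$crs_id))
      }
      res <- max(ref$grid$pixel_size, m$grid$pixel_size)
      rung <- resolution_ladder(ref, m, res,
                                min_valid_frac = config$min_valid_frac)[[1L]]
      c_cmp <- rung$c_ref; m_cmp <- rung$m_map
    } else {
      c_cmp <- ref; m_cmp <- m
    }
    g <- c_cmp$grid
    msk <- if (!is.null(mask)) {
      if (grids_identical(mask$grid, g)) mask else
        mask_to_grid(mask, g, config$forest_threshold)
    }
    zns <- if (!is.null(zones)) {
      if (grids_identical(zones$grid, g)) zones else zones_to_grid(zones, g)
    }

    st <- do.call(rbind, lapply(config$strata, function(s) {
      pair_stats(common_valid_pairs(c_cmp, m_cmp, msk, s),
                 stratum = s, resolution = g$pixel_size)
    }))
    st <- cbind(reference = config$reference, map_id = label, st)
    all_stats[[label]] <- st
    log_lines <- c(log_lines, sprintf(
      "pair %s vs %s at %g m: n(ALL) = %d, both-zero FNI cells = %s",
      config$reference, label, g$pixel_size, st$n[st$stratum == "ALL"],
      paste(st$n_both_zero, collapse = "/")))

    write_raster(difference_map(c_cmp, m_cmp),
                 file.path(config$out_dir, sprintf("diff_%s.asc", label)))
    write_raster(fni_map(c_cmp, m_cmp),
                 file.path(config$out_dir, sprintf("fni_%s.asc", label)))
    if (!is.null(msk)) {
      write_histograms(m_cmp, label, msk)
      all_state[[label]] <- state_totals(m_cmp, msk, map_id = label)
    }
    if (!is.null(zns)) {
      za <- zonal_summaries(c_cmp, zns, msk, "ALL", map_id = config$reference)
      zb <- zonal_summaries(m_cmp, zns, msk, "ALL", map_id = label)
      all_zonal[[paste0(config$reference, "@", label)]] <- za
      all_zonal[[label]] <- zb
      for (on in c("mean", "total")) {
        cz <- compare_zonal(za, zb, on)
        all_zcmp[[paste(label, on)]] <-
          data.frame(reference = config$reference, map_id = label, on = on,
                     n_zones = cz$n_zones, slope = cz$slope,
                     intercept = cz$intercept, r2 = cz$r2, mbe = cz$mbe)
      }
    }

    ladder_res <- config$ladder[config$ladder >= g$pixel_size]
    if (length(ladder_res) > 0L) {
      lad <- resolution_ladder(c_cmp, m_cmp, ladder_res,
                               min_valid_frac = config$min_valid_frac)
      curve <- convergence_curve(lad, mask = msk, zones = zns,
                                 forest_threshold = config$forest_threshold)
      all_curves[[label]] <- cbind(reference = config$reference,
                                   map_id = label, curve)
      conv_scales[[label]] <- convergence_scale(curve, config$epsilon)
      log_lines <- c(log_lines, sprintf(
        "pair %s vs %s: convergence scale at epsilon %g = %s m",
        config$reference, label, config$epsilon,
        format(conv_scales[[label]])))
    }
  }

  tables <- list(pair_stats = do.call(rbind, all_stats),
                 state_totals = do.call(rbind, all_state),
                 zonal = do.call(rbind, all_zonal),
                 zonal_comparisons = do.call(rbind, all_zcmp),
                 convergence = do.call(rbind, all_curves),
                 convergence_scale = unlist(conv_scales),
                 out_dir = config$out_dir)
  write_tbl <- function(x, name) {
    if (!is.null(x)) utils::write.csv(x, file.path(config$out_dir, name),
                                      row.names = FALSE)
  }
  write_tbl(tables$pair_stats, "pair_stats.csv")
  write_tbl(tables$state_totals, "state_totals.csv")
  write_tbl(tables$zonal, "zonal_summaries.csv")
  write_tbl(tables$zonal_comparisons, "zonal_comparison.csv")
  write_tbl(tables$convergence, "convergence.csv")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(tables)
}

#' Materialize a synthetic landscape on disk
#'
#' Writes `truth.asc`, `degraded.asc`, `mask.asc`, `zones.asc` and a
#' `manifest.txt` (key-value, DCF) holding every generating parameter,
#' so the run is fully reproducible from the manifest alone.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory.
#' @param n_rows_z,n_cols_z Zone tiling (see [gen_zones()]).
#' @return Invisibly, a list with the four generated objects and the
#'   file paths.
#' @export
run_synth <- function(config, out_dir, n_rows_z = 4L, n_cols_z = 4L) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- gen_truth(config)
  mask <- gen_mask(truth, config)
  degraded <- degrade(truth, mask, config)
  zones <- gen_zones(config$grid, n_rows_z, n_cols_z)
  paths <- file.path(out_dir, c(truth = "truth.asc", degraded = "degraded.asc",
                                mask = "mask.asc", zones = "zones.asc"))
  names(paths) <- c("truth", "degraded", "mask", "zones")
  write_raster(truth, paths[["truth"]])
  write_raster(degraded, paths[["degraded"]])
  write_raster(mask, paths[["mask"]])
  write_raster(zones, paths[["zones"]])
  write_manifest(config, file.path(out_dir, "manifest.txt"),
                 n_rows_z = n_rows_z, n_cols_z = n_cols_z)
  invisible(list(truth = truth, degraded = degraded, mask = mask,
                 zones = zones, paths = paths,
                 manifest = file.path(out_dir, "manifest.txt")))
}

#' Write / read a synthetic-landscape manifest
#'
#' The manifest is a DCF key-value text file carrying the full
#' [synth_config()] (grid geometry included) plus the zone tiling;
#' `read_manifest()` reconstructs an identical config.
#'
#' @param config A [synth_config()].
#' @param path Manifest file path.
#' @param ... Extra scalar fields to record (e.g. zone tiling).
#' @return `write_manifest()`: `path`, invisibly. `read_manifest()`: a
#'   list with `config` and any extra fields.
#' @export
write_manifest <- function(config, path, ...) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$grid
  fields <- c(list(origin_x = g$origin_x, origin_y = g$origin_y,
                   pixel_size = g$pixel_size, n_rows = g$n_rows,
                   n_cols = g$n_cols, crs_id = g$crs_id),
              config[setdiff(names(config), "grid")],
              list(...))
  df <- as.data.frame(lapply(fields, function(x) format(x, digits = 17)),
                      stringsAsFactors = FALSE)
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- function(x) as.numeric(x)
  g <- grid_spec(num(raw$origin_x), num(raw$origin_y), num(raw$pixel_size),
                 num(raw$n_rows), num(raw$n_cols), crs_id = raw$crs_id)
  cfg <- synth_config(grid = g, seed = num(raw$seed),
                      field_meanlog = num(raw$field_meanlog),
                      field_sdlog = num(raw$field_sdlog),
                      correlation_length = num(raw$correlation_length),
                      forest_fraction = num(raw$forest_fraction),
                      gain = num(raw$gain), offset = num(raw$offset),
                      noise_sd = num(raw$noise_sd),
                      ceiling = num(raw$ceiling),
                      native_resolution = num(raw$native_resolution),
                      zero_outside_forest = as.logical(raw$zero_outside_forest),
                      mask_lag_flip_frac = num(raw$mask_lag_flip_frac),
                      truth_max = num(raw$truth_max))
  extra <- raw[setdiff(names(raw),
                       c("origin_x", "origin_y", "pixel_size", "n_rows",
                         "n_cols", "crs_id", names(cfg)))]
  c(list(config = cfg), extra)
}
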