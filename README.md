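# agbcompare

Multi-scale intercomparison of gridded aboveground biomass (AGB) maps.

Continental-scale biomass products (InSAR-, MODIS- or fusion-based, 30 m
to 250 m native resolution) disagree strongly with high-resolution,
lidar-derived reference maps at the pixel level, yet appear to converge
once aggregated to kilometre scales — unless the disagreement is a
systematic bias, which no amount of coarsening removes. `agbcompare`
gives carbon-accounting and remote-sensing analysts the tooling to
quantify exactly this: where two biomass maps differ, by how much, at
which spatial scale the differences wash out, and what that does to
county- and state-level carbon totals.

## What it computes

For a reference map `C` (e.g. a lidar-derived product) and a comparison
map `M` over `n` co-registered cells (biomass density in Mg ha⁻¹):

- **R²** = 1 − Σ(Cᵢ − Mᵢ)² / Σ(Mᵢ − M̄)² — agreement about the 1:1 line
  (not a squared correlation; can be negative; asymmetric in C and M),
- **RMSD** = √(Σ(Cᵢ − Mᵢ)²/n) and **RMSD%** = 100·RMSD/C̄,
- **MBE** = Σ(Cᵢ − Mᵢ)/n — signed bias, positive when the reference is
  higher,
- **FNI** (Fuzzy Numerical Index) = mean of 1 − |Cᵢ − Mᵢ|/max(Cᵢ, Mᵢ),
  a per-cell relative similarity in [0, 1] (0 = fully distinct,
  1 = fully identical), also available as a similarity map,

stratified over forest / non-forest / combined cells of a land-cover
mask, plus:

- block-mean aggregation and area-weighted regridding with explicit
  nodata rules; forest-mask coarsening by an inclusive 20 %
  forest-fraction threshold,
- 10 Mg ha⁻¹ biomass histograms (0–400 Mg ha⁻¹, optional
  zero-exclusion) and signed difference maps,
- zonal (county) and whole-map (state) accounting: compared area,
  mean density, and totals in Tg (mean Mg ha⁻¹ × area km² × 10⁻⁴),
- agreement as a function of resolution along a 250 m → 4 km ladder,
  with detection of the first scale of sustained convergence,
- a seeded synthetic-landscape generator (autocorrelated lognormal
  biomass field, biomass-correlated forest mask, and a configurable
  degraded "continental product": gain/offset bias, noise, 250 Mg ha⁻¹
  saturation ceiling, zeroing outside a time-lagged mask, coarser
  native grid) so the whole pipeline is testable end to end.

Rasters are read and written as single-band ESRI ASCII grids
(`.asc`/`.txt`), with nodata sentinels honored; masks use
FOREST = 1 / NONFOREST = 0 / NODATA = 255.

## Worked example

```r
library(agbcompare)

cfg     <- synth_config(grid = grid_spec(0, 128 * 30, 30, 128, 128), seed = 42)
truth   <- gen_truth(cfg)              # "lidar reference" map, 30 m
mask    <- gen_mask(truth, cfg)        # forest / non-forest mask
product <- degrade(truth, mask, cfg)   # biased, noisy, saturated product
zones   <- gen_zones(raster_grid(truth), 4, 4)

stratified_pair_stats(truth, product, mask)
#>     stratum resolution     n      r2 rmsd rmsd_pct  mbe    fni
#>         ALL         30 16384   0.299 66.5     63.0 47.8 0.3246
#>      FOREST         30  7537  -0.305 84.8     47.2 55.5 0.6795
#>   NONFOREST         30  8847 -26.145 45.6    106.9 41.2 0.0223
```

The degraded product is similar to the reference inside forest
(FNI 0.68) and almost fully dissimilar outside it (FNI 0.02) because,
like real continental products, it predicts no biomass outside its
(time-lagged) forest mask; the positive MBE says the reference is
~48 Mg ha⁻¹ higher on average.

```r
curve <- convergence_curve(
  resolution_ladder(truth, product, c(250, 500, 1000, 4000)),
  mask = mask, zones = zones)
curve[, c("resolution", "n_cells", "r2_mean", "rmsd_mean", "mbe_mean", "fni_mean")]
#>   resolution n_cells r2_mean rmsd_mean mbe_mean fni_mean
#>          250     256   0.215      58.4     48.6    0.393
#>          500      64  -0.114      54.2     48.3    0.452
#>         1000      16  -1.927      49.1     47.8    0.518
#>         4000       1      NA      47.8     47.8    0.548

convergence_scale(curve, epsilon = 5)
#> [1] NA
```

RMSD shrinks with coarsening as the noise-like disagreement averages
out — but only down to the ~48 Mg ha⁻¹ bias floor, which is identical
at every rung, so the pair never reaches the 5 Mg ha⁻¹ convergence
criterion (`NA`): a systematic bias cannot be aggregated away.

```r
state_totals(truth, mask, map_id = "truth")
#>   zone_id map_id   stratum n_cells area_km2 mean_density total_biomass_tg
#>         1  truth    FOREST    7537    6.783       179.59          0.12182
#>         1  truth NONFOREST    8847    7.962        42.66          0.03397
#>         1  truth       ALL   16384   14.746       105.65          0.15579
```

`run_synth()` / `run_compare()` assemble the full report bundle (CSV
tables, difference and FNI rasters, histograms, run log); a thin CLI
over them ships in `inst/cli/agbcompare.R`.

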