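---
title: "Methods: multi-scale intercomparison of biomass maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale intercomparison of biomass maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agbcompare)
```

## The problem

High-resolution (30 m) lidar-derived aboveground-biomass maps and
continental-scale products built from optical/radar imagery and forest
inventories disagree strongly at the pixel level, and the disagreement
has two qualitatively different components: noise-like scatter, which
averages out under spatial aggregation, and systematic bias (saturation
above ~250 Mg ha⁻¹, absent predictions outside forest masks,
calibration offsets), which does not. `agbcompare` implements the
comparison machinery that separates the two: pairwise agreement
statistics stratified by a forest mask, zonal and whole-map carbon
accounting, and re-evaluation of agreement along a ladder of coarser
resolutions.

Everything operates on a deliberately minimal raster model: a planar
grid (`grid_spec`) with a top-left origin, square pixels, and an opaque
`crs_id`. The pipeline assumes its inputs have already been warped into
one shared planar reference system; only grid-to-grid resampling is
performed here, never datum or projection transformations. This keeps
the finding-bearing computation — which starts *after* warping — free
of a GDAL dependency.

## The comparison statistics

For reference map $C$ and comparison map $M$ over $n$ paired cells:

$$R^2 = 1 - \frac{\sum_i (C_i - M_i)^2}{\sum_i (M_i - \bar M)^2},
\qquad
\mathrm{RMSD} = \sqrt{\tfrac{1}{n}\sum_i (C_i - M_i)^2},
\qquad
\mathrm{RMSD\%} = 100\,\frac{\mathrm{RMSD}}{\bar C},$$

$$\mathrm{MBE} = \tfrac{1}{n}\sum_i (C_i - M_i),
\qquad
\mathrm{FNI} = \tfrac{1}{n}\sum_i
  \left(1 - \frac{|C_i - M_i|}{\max(C_i, M_i)}\right).$$

Points worth making explicit:

* **$R^2$ is agreement about the 1:1 line**, not a squared correlation.
  It is negative whenever the maps disagree more than $M$ varies about
  its own mean, and it is asymmetric: $M$ normalizes the denominator
  while RMSD% is normalized by $\bar C$. The reference map is therefore
  always explicit in this package (`run_config(reference = ...)`), never
  inferred.
* **MBE is implemented with the $C - M$ sign**: positive means the
  reference map is higher. Published county-level comparisons in this
  literature sometimes report the opposite orientation without
  redefining the formula; we implement the formula verbatim and label
  the convention in every report log rather than guess.
* **FNI** is a mean per-cell *relative* similarity in $[0, 1]$. The
  $C_i = M_i = 0$ cell is $0/0$ and undefined by the formula. Two
  identical zeros are fully similar, so the term defaults to 1; it is
  configurable (`both_zero_term`), and the count of such cells is
  reported alongside every FNI value because zero-inflated products
  (those that predict nothing outside forest) make the choice
  consequential.
* Degenerate inputs produce explicit `NA`s in report tables (empty
  strata, constant $M$ for $R^2$, $\bar C = 0$ for RMSD%), never silent
  zeros; the scalar functions themselves error instead, so misuse is
  loud in scripts.

Zeros are *included* in pixel statistics by default — maps that predict
zero outside forests are being evaluated on exactly those cells — with
`include_zeros = FALSE` available on histograms to mirror the common
zero-excluded inset convention.

## Aggregation and regridding

Block-mean aggregation (`aggregate_mean`) is the workhorse: each
`f × f` block becomes one output cell holding the arithmetic mean of
its valid cells. Because biomass is a density, the block mean conserves
totals; the test suite checks mean preservation to 1e-9 on gap-free
rasters and multiplicative composition
(`aggregate(aggregate(r, a), b) = aggregate(r, ab)`).

Numerical and edge conventions, chosen once and tested:

* Cell `(row, col)` covers the half-open square `[x, x+s) × (y−s, y]`;
  histogram bins are likewise half-open and left-inclusive, so a value
  of exactly 10 falls in the [10, 20) bin and values at or above the
  range top land in a separately reported overflow bin.
* Factors that do not divide the grid **pad with nodata, never
  truncate** — truncation would silently discard biomass.
* A block becomes nodata when its valid fraction (of `f²`, padding
  counted invalid) falls below `min_valid_frac`; the default 0.5 is a
  judgment call (no canonical value exists) and is configurable and
  logged.
* Forest masks aggregate by forest fraction against an **inclusive**
  threshold: a block at exactly 20 % forest is forest. The 20 % default
  follows the "more than 20 percent tree dominance" forest definition
  of NLCD-style land-cover legends; inclusivity matches the way such
  thresholds are stated ("a 20 % threshold"), and is pinned by a test.
* Zone rasters aggregate by majority label with ties broken toward the
  smaller label — arbitrary but deterministic.

`resample_to_grid(method = "area_weighted")` generalizes block means to
arbitrary aligned-CRS targets by overlap-area weighting; since grids
are axis-aligned the 2-D overlaps factor into 1-D interval overlaps,
implemented as two small matrix products. On aligned integer-factor
targets it reproduces `aggregate_mean` exactly, which the tests enforce
against an independent brute-force rectangle-intersection oracle on
randomly shifted and scaled targets with random nodata. `nearest` is
provided for sensitivity checks and is the only method allowed for
categorical rasters. No named resampling kernel is canonical for this
kind of comparison; area-weighted averaging is the default here because
it is the unique choice that conserves totals of a density variable.

## Zonal and state accounting

Summaries report *compared area* — valid-cell count × pixel area — not
nominal polygon area, so products with coverage gaps are accounted on
the cells they actually predict, and `n_cells` is always reported so
gaps are detectable. Units: Mg ha⁻¹ × km² × 100 ha km⁻² × 10⁻⁶ Tg Mg⁻¹,
i.e. `total_from_mean(100, 100) = 1` Tg. Zone membership is whole-cell
by cell center (zones are label rasters); cells are not split at zone
boundaries. County-level comparisons fit the comparison map on the
reference by ordinary least squares and report $R^2$ and MBE in the
same orientation as the pixel statistics. Totals are
aggregation-invariant (zonal totals at native resolution equal totals
after any exact-factor block mean), which the tests verify — this is
the mechanism that makes total-biomass convergence curves flat apart
from mask/boundary effects.

## The resolution ladder

`resolution_ladder` brings both maps to each target resolution
(default 250 m, 500 m, 1 km, 4 km, mirroring the scales at which such
products are commonly compared) on a shared grid anchored at the
reference map's origin; masks are re-thresholded per rung from their
native resolution (via the forest-fraction route, identical to
`aggregate_mask` for integer factors), and zones are re-gridded by
area-majority. `convergence_scale` reports the first rung from which
cell-level RMSD stays at or below `epsilon` through the coarsest rung —
a *sustained* crossing, so a rebound postpones convergence. There is no
canonical epsilon for "near-perfect" agreement; the default of
5 Mg ha⁻¹ is explicitly arbitrary and user-set.

Two properties anchor the interpretation and are tested: additive
constant bias is exactly invariant under block means (MBE identical at
every rung), and independent cell noise shrinks roughly with the square
root of the number of cells merged, so RMSD for a truth-vs-noisy pair
decreases monotonically along the ladder up to sampling noise.

## What the synthetic generator emulates — and what it does not

`gen_truth` smooths seeded white noise with a separable Gaussian kernel
(reflecting edges), restandardizes, and exponentiates:
`exp(meanlog + sdlog·z)`, clipped to [0, 450] Mg ha⁻¹. Smoothing by
banded matrices was chosen over spectral synthesis as simpler,
dependency-free and adequate for testing; the field is stationary and
isotropic, which real landscapes are not. Defaults (`meanlog = 4.3`,
`sdlog = 0.9`, correlation length 150 m) give a right-skewed marginal
with median ~74 Mg ha⁻¹ and a tail past 400 — the shape seen in
temperate-state biomass histograms — but are *plausible*, not fitted
to any real map. The forest mask takes the top-biomass quantile at
`forest_fraction` (default 0.46, roughly the forest share of a
mid-Atlantic state), so mask and biomass are correlated by
construction.

`degrade` applies, in order: gain/offset calibration bias (defaults
0.85 and −10 Mg ha⁻¹, a product biased low), additive Gaussian noise
(30 Mg ha⁻¹), clipping at zero, a saturation ceiling (250 Mg ha⁻¹),
zeroing outside a lag-perturbed copy of the mask (5 % of cells
class-flipped), and block-mean coarsening to the product's native
resolution. Each mechanism is independently switch-off-able, which is
what makes parameter-recovery tests possible: with noise off, the
injected offset is recovered exactly by −MBE on cells clear of the
zero clip; with noise on, to sampling tolerance. All randomness derives
from the explicit config seed (truth, noise and mask-lag draws use
distinct seed offsets) and the caller's RNG state is saved and
restored.

What passing tests on this generator do **not** show: behaviour under
anisotropic or non-stationary spatial structure, real land-cover
legends, registration error between products, or non-Gaussian error
processes. The generator exists to verify the *mechanics* of the
pipeline (conservation, stratification, scaling laws), not to emulate
any particular state's spatial statistics.

## Problem sizes and determinism

The test suite exercises parameter recovery on 256×256 grids
(~65k cells, chosen so that a 30 Mg ha⁻¹ noise level leaves the mean
bias estimable to well under 0.5 Mg ha⁻¹), convergence-shape properties
on 128×128 grids over 20 seeds, and oracle equivalences on exhaustive
≤10×10 grids over 200 seeded cases; all stochastic tests fix their
seeds and the whole suite runs in well under a minute. Exact identities
(mass conservation, bias invariance, oracle equivalence) are asserted
at 1e-9 or tighter; statistical properties at explicitly stated
sampling tolerances.

## Known limitations

* No reprojection: inputs must share a planar CRS (`crs_id` equality is
  checked, nothing more). Rotated or sheared grids and non-square
  pixels are unsupported.
* File I/O is ESRI ASCII grid only — text-based and universally
  convertible (`gdal_translate -of AAIGrid`), but bulky for very large
  rasters; GeoTIFF is not read directly.
* Vector zone polygons are out of scope; zones enter as label rasters,
  and county means consequently weight boundary cells wholly by their
  center, not by within-zone area fraction.
* FNI is the per-pixel index only; neighbourhood (multi-scale fuzzy)
  similarity variants are not implemented.
* No significance testing on statistic differences, and no uncertainty
  propagation from the maps' own error layers.
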