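Package: agbcompare
Title: Multi-Scale Intercomparison of Aboveground Biomass Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing gridded aboveground biomass (AGB) density
    maps across spatial scales, in the style of lidar-reference versus
    continental-product intercomparisons. Provides a lightweight planar
    raster data model with ESRI ASCII grid I/O,
    block-mean aggregation with nodata handling, threshold-based
    forest-mask aggregation, area-weighted regridding, pairwise map
    statistics (R-squared, RMSD, RMSD%, mean bias error, and the Fuzzy
    Numerical Index), stratified histograms and difference maps, zonal
    (county/state) mean and total biomass accounting with Mg/ha-to-Tg
    unit conversion, resolution-ladder convergence analysis, and a
    seeded synthetic-landscape generator for end-to-end testing of the
    whole pipeline without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
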