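Package: ugli
Title: Dasymetric Population Mapping from Impervious-Surface Weights
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Distributes census zone-level population counts across 30-m
    pixels in proportion to non-road, residential impervious surface
    fraction, with exact per-zone population conservation. Includes the
    three-rule residential masking of the impervious layer (low-fraction
    filter, road-class removal, zero-population block removal),
    rasterization of census polygons by the pixel-center rule, county
    clipping, census-vintage county-code harmonization, a hazard-exposure
    validation workflow (binarized wildfire and flood rasters,
    polygonization, zonal population sums, an areal-weighting baseline and
    percent differences), and a seeded synthetic-county generator so the
    full pipeline is testable without external downloads. Rasters are read
    and written as Esri ASCII grids with a CRS sidecar; vector zones as
    GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
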