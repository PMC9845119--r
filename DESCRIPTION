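Package: crowncarbon
Title: Tree Crown Separation and Per-Tree Carbon Mapping from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for turning binary tree-crown segmentation rasters into
    per-tree carbon estimates and per-hectare maps. Separates clumped crowns
    with a detect-centre-and-relabel (DCR) algorithm built on an exact
    Euclidean distance transform, converts crown diameter to stem diameter
    with major-axis regression (linear, or logarithmic with Baskerville
    correction), applies land-cover-specific allometric equations for
    aboveground biomass and carbon, aggregates trees to hectare grids of
    density, canopy cover and carbon density, and quantifies uncertainty with
    bias metrics, area-weighted class biases and a half-sample ensemble
    procedure. Includes a synthetic-scene generator so the full chain is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage
Config/testthat/edition: 3
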