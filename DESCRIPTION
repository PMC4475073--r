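Package: hexconn
Title: Suitability-Weighted Graph Connectivity and Focal-Landscape Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies habitat connectivity under joint habitat-configuration and
    climate-change effects using graph-theoretic habitat availability indices.
    Implements the Probability of Connectivity (PC) and Integral Index of
    Connectivity (IIC) with suitability-weighted patch attributes, a negative
    exponential dispersal kernel, a two-scale analysis on hexagonal focal
    landscapes (local PC numerator per cell, regional node-removal Delta-IIC),
    temporal differencing of regional importance across climate periods, and a
    six-class conservation/restoration strategy classifier. Ships a synthetic
    landscape generator (fragmented binary habitat, temporally drifting
    suitability surfaces) so the full pipeline is testable without external
    data, plus raster/vector text I/O and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
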