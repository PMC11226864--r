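Package: spixel
Title: Rasterization Preprocessing for Single-Cell Resolution Spatial Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates single-cell resolution spatial omics measurements
    (gene expression or cell-type labels) into equally sized square or
    hexagonal pixels at a user-chosen resolution, so that downstream spatial
    statistics scale with the number of pixels rather than the number of
    cells. Includes rotation-permutation consensus voting for robust
    spatially variable gene detection with a Moran's I permutation test,
    a relative-enrichment / noncentral-hypergeometric affinity analysis of
    pairwise cell-type co-enrichment across length scales, and simulators
    for circular spatial expression patterns and nested cell-type
    arrangements with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
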