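Package: spinereg
Title: Coarse-to-Fine Registration of Cross-Source Spinal Surface Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Rigid registration of pre-operative (CT-derived) and
    intra-operative (scanned) spine surface point clouds that differ in
    density, initial pose and share only a small overlapping patch.
    Implements a coarse stage built on per-point surface-variation
    curvature features, a learned point-matching network (hierarchical
    set-abstraction encoder plus self/cross graph attention, trained
    with Adam), farthest-point-sampled candidate local regions and
    RANSAC pose estimation, followed by point-to-point ICP refinement.
    Ships a parametric vertebra-phantom generator so training,
    registration and noise-robustness experiments run end-to-end
    without external data, plus readers and writers for PLY, PCD and
    XYZ point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
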