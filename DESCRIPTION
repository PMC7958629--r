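Package: rbcseg
Title: Two-Stage Segmentation and Morphometry of Erythrocyte Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments red blood cells in bright-field microscope images by a
    two-stage procedure: median/mean/bilateral filtering and rolling-ball
    background flattening, Otsu thresholding with an inverted Euclidean
    distance map and watershed flooding to split touching cells, then
    per-cell local re-thresholding with contour extraction and long/short
    axis morphometry. Includes a parametric generator of ground-truthed
    artificial blood-smear images and a pixel-level evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
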