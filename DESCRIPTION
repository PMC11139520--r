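Package: cellasr
Title: Segmentation and Identity Recognition of Densely Packed Cells in 3D
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated segmentation-and-recognition pipeline for whole-body
    cells in 3D fluorescence image stacks of small model organisms such as
    L1-stage C. elegans. Instance segmentation regresses a per-voxel
    displacement vector field (the offset of every voxel to its nearest
    background voxel) with a small 3D encoder-decoder network, converts it to
    a Euclidean distance map, and separates touching nuclei by seeded
    watershed. Cell identities are then assigned by matching segmented
    centroids against a three-part statistical atlas (average spatial
    positions, per-axis positional variability, and shape-context based
    topological variability) through annealed robust point matching,
    piecewise-affine mapping, and consensus bipartite assignment. Includes
    segmentation and recognition evaluation metrics, synthetic phantom and
    worm generators for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
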