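Package: epitopo
Title: Network-Based Analysis of Epithelial Topology in Segmented Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the organization of proliferating epithelia from
    2D segmented label images. Extracts per-cell geometric features and
    cell-contact-network features (40 image-level characteristics), builds
    thresholded cell-correlation networks, compares polygon (cell-side)
    distributions between two conditions by MANOVA, and selects the most
    discriminant features with a beam search driven by a Calinski-Harabasz
    style separation descriptor on a 2D PCA projection, validated against a
    group-label randomization null. Includes a synthetic epithelial mosaic
    generator (hardcore Voronoi tessellation with Lloyd relaxation and a
    controllable polygon-distribution shift) so the whole pipeline runs
    without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    tiff,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
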