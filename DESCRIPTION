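Package: dhmpheno
Title: Label-Free Single-Cell Phenotyping from Quantitative Phase Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for digital holographic microscopy (DHM) phase
    images of suspended cells: median background estimation and subtraction,
    threshold-based segmentation with border-following contour extraction,
    single-cell patch extraction, a morphological feature bank plus an optional
    convolutional embedding channel, balanced cross-validated phenotype
    classification (random forest, RBF support vector machine, k-nearest
    neighbours, single-hidden-layer neural network), spike-in mixture
    quantification, UMAP embedding with kernel-density contours, single-linkage
    sample dendrograms on the most important features, and a tumor
    heterogeneity score (mean squared distance to the sample centroid in the
    embedding) with rank-based group comparisons. Includes a synthetic phantom
    generator producing phase frames with known ground truth so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    Rcpp,
    class,
    e1071,
    grDevices,
    graphics,
    jsonlite,
    nnet,
    randomForest,
    stats,
    tiff,
    utils,
    uwot,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    cluster,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
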