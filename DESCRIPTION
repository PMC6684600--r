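Package: tabimage
Title: Transform Tabular Omics Samples into Images for Convolutional
    Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts non-image tabular samples (such as gene-expression
    vectors) into well-organized grayscale images by embedding the features
    into a 2D plane with t-SNE or kernel PCA, enclosing them in a
    minimum-area rectangle found by rotating calipers over the convex hull,
    rotating the plane to frame the image, and discretizing feature
    coordinates to pixels with collision averaging. Includes a two-branch
    parallel convolutional neural network classifier for the resulting
    image stacks, validation-driven selection between per-feature and
    global min-max normalization, a seeded random-search tuning harness,
    fully specified synthetic benchmark generators (ringnorm,
    Madelon-like, correlated blocks) and a reproducible stratified
    80:10:10 split.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    kernlab,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    rpart,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
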