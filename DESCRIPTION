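Package: seednet
Title: Lightweight Residual Networks for Maize Seed Variety Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Single-seed maize variety classification from RGB images with a
    configurable family of 50-layer bottleneck residual networks: stage-based
    (ResStage) reorganisation of the early stages, efficient channel attention
    and depthwise-separable convolutions in the later residual blocks, and a
    mixed Swish/PReLU activation placement. Includes exact trainable-parameter
    and multiply-accumulate accounting for every ablation variant, a
    multi-seed scene segmentation pipeline (automatic global thresholding,
    morphological cleaning, centroid-centred crop extraction), minibatch SGD
    training with stratified k-fold cross-validation and standard
    classification metrics, Grad-CAM heatmaps, and a synthetic seed-image
    generator for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    withr,
    EBImage,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
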