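Package: axofoci
Title: Quantification of Meiotic DSB-Protein Foci Relative to Chromosome
    Axes in 3D Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying punctate recombination-protein foci
    (e.g. SPO11-1 immunosignals) relative to axial-element labelled
    chromosome axes (e.g. DSY2, ZYP1) in multi-channel 3D fluorescence
    z-stacks. Implements histogram-based threshold selection, rolling-ball
    background subtraction, 3D median filtering and seeded 3D spot
    segmentation with per-object geometric and intensity measurements;
    top-hat filtering, trainable voxel classification, Hessian tubeness
    enhancement, topology-preserving 3D skeletonization and branch
    tracing of chromosome axes; anisotropic 3D Euclidean distance maps
    and strict zero-distance axis-association classification; axis
    length, circle-fit curvature (kappa = 1/r) and synapsis-fraction
    metrics; and a ground-truthed synthetic nucleus simulator so every
    stage is verifiable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
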