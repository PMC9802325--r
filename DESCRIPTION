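Package: trabnet
Title: Network Analysis of Trabecular Bone in Micro-CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the spatial network formed by trabecular bone from 2D
    grayscale micro-CT slices (contrast adjustment, binarization, cleaning,
    topology-preserving thinning, junction/endpoint detection and ridge
    tracing), computes per-slice graph statistics including clustering
    coefficient, characteristic path length and small-worldness against a
    matched random reference, 2D morphometric analogues (bone area fraction,
    local thickness/separation, box-counting fractal dimension), aggregates
    metrics into depth profiles with unpaired group comparisons, and classifies
    control versus osteoarthritic regimes with a compact convolutional neural
    network fed either raw slices or rendered extracted networks. A synthetic
    trabecular phantom generator with exact ground-truth network topology makes
    the whole pipeline testable without patient scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    png,
    tiff,
    ggplot2,
    rlang,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'imageproc.R'
    'graph.R'
    'io.R'
    'cnn.R'
    'depth.R'
    'morpho.R'
    'metrics.R'
    'phantom.R'
    'cli.R'
    'trabnet-package.R'
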