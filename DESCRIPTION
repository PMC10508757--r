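Package: SpotSuite
Title: Spot Detection, Consensus Labeling and Barcode Decoding for
    Image-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-molecule FISH and multiplexed
    (MERFISH/seqFISH-style) spatial transcriptomics images. Provides
    classical spot detectors with subpixel Gaussian refinement, weakly
    supervised consensus labeling of multi-annotator detections via an
    EM-fitted Bernoulli generative model, a fully convolutional
    pixel-classification plus subpixel-regression spot detection model,
    mutual-nearest-neighbor benchmarking, and probabilistic combinatorial
    barcode decoding with a mixture of relaxed Bernoulli distributions fit
    by gradient-based variational inference, together with simulators for
    spot images, detection matrices and barcode traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Matrix,
    igraph,
    minpack.lm,
    tiff,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    yaml,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
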