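Package: illumfield
Title: Retrospective Illumination Correction and Quality Assessment for
    High-Content Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-batch illumination correction functions (ICFs) for
    high-throughput fluorescence microscopy by mean projection of all images
    in a batch followed by median-filter smoothing, and corrects images by
    pixelwise division.  Includes quality control of the estimated functions
    (percent variation, residual-relief roughness, cell-density uniformity,
    cross-batch outlier detection), univariate assay evaluation with standard
    and one-tailed Z'-factors, a minimal image-based profiling chain with
    leave-one-compound-out nearest-neighbour mechanism-of-action
    classification, and a ground-truth plate simulator with parametric
    multiplicative shading fields for validating the whole pipeline.
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
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
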