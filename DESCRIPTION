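Package: mammocalc
Title: Cascaded Detection of Microcalcifications in Mammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual microcalcifications and microcalcification
    clusters in 2-D grayscale mammograms with a two-stage cascade: adaptive
    breast-region segmentation, a random-forest classifier over multi-scale
    Hessian-eigenvalue features, and a discriminative restricted Boltzmann
    machine over raw image patches, followed by two cluster-grouping rules
    (pairwise-distance grouping and cumulative local probability). Includes
    a synthetic phantom generator with full ground truth, ROC,
    precision-recall and FROC evaluation utilities, and a command-line
    pipeline. Results are returned as tibbles so they compose with the
    tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
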