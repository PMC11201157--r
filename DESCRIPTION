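Package: scalpelseg
Title: Imbalance-Aware Semantic Segmentation of Surgical Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semantic segmentation of laparoscopic surgical scenes
    under severe class imbalance. Provides class-weighted and combined loss
    functions (cross-entropy, focal, Dice, Tversky and their convex
    combinations), pluggable activation functions (ReLU, GELU, Swish), a
    depth-configurable encoder-decoder segmentation network trained with
    SGDM or Adam under a piecewise learning-rate schedule, per-class and
    boundary-F1 evaluation metrics, median-frequency class weighting, and a
    synthetic scene generator that reproduces the presence-frequency and
    pixel-share structure of 13-class cholecystectomy datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
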