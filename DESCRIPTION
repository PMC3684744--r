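Package: dispersyn
Title: Trait-Based Inference of Dispersal Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect dispersal syndromes and predict species-level
    dispersal from life-history traits. Builds the four classical butterfly
    dispersal measurements (mean dispersal distance and long-distance
    dispersal frequency from fitted movement kernels, dispersal propensity
    from mark-release-recapture residency, and gene flow from F_ST),
    detects trait syndromes by two-stage exhaustive AICc model selection
    with quadratic and interaction terms, quantifies predictive quality by
    cross-validated rightness and imprecision against a wing-size-only
    reference, partitions explained variance among traits by the
    Lindeman-Merenda-Gold decomposition, checks phylogenetic signal by
    phylogenetic generalized least squares with Pagel's lambda, and
    predicts dispersal for species lacking measurements. A synthetic-data
    generator makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
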