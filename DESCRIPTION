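Package: foraynet
Title: Stage-Structured Social Network Analysis for Cooperatively Breeding Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds simple-ratio-index association networks from group-by-individual
    co-detection data for a territorial, cooperatively breeding bird, computes
    per-individual network position metrics (binary degree, inverse-weight betweenness,
    local clustering, unique sampling points), applies spatial inclusion criteria from
    territory covariates, and tests for life-history-stage differences with sequential
    ANOVA, Tukey HSD contrasts and Brown-Forsythe homogeneity statistics referenced
    against location-restricted checkerboard (data-stream) permutation null models.
    Includes a stage-structured population and playback-survey simulator with known
    ground truth so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
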