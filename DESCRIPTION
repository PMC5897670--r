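Package: depna
Title: Dependency Network Analysis for ROI Time-Series Influence Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Correlation-based dependency network analysis for regions-of-
    interest (ROI) time series. Decomposes pairwise Pearson correlations with
    third-node partial correlations to quantify each node's influence on every
    other connection, builds the asymmetric dependency matrix and node
    "influencing degree", and aggregates influence within and between a-priori
    sub-networks. Includes selection of contrasting task epochs from continuous
    emotion-rating traces, paired condition contrasts with Benjamini-Hochberg
    false-discovery-rate control, edgewise contrast graphs with BrainNet
    Viewer and GraphML export, behavior correlations with outlier exclusion,
    random-network specificity bootstraps, spherical-ROI signal extraction
    from NIfTI volumes, and a seeded synthetic multi-subject cohort generator
    with a planted influence hub for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
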