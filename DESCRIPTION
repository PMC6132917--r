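Package: painnet
Title: Resting-State Functional Network Topology of Pain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for analysing pain-related resting-state functional
    brain networks from region-of-interest (ROI) time series. Builds
    motion-scrubbed Fisher-z correlation adjacency matrices, computes
    weighted global efficiency and Brandes betweenness centrality for the
    whole brain and for named subnetworks (a 16-node pain network derived
    from the positive-weight regions of the neural pain signature, and a
    58-node default mode network), and runs the accompanying statistical
    layer: Mann-Whitney U tests, 2x2 Pearson chi-square, covariate-adjusted
    group comparisons (MANCOVA-style), and hierarchical forward-stepwise
    regression with a forced motion covariate. Includes a synthetic cohort
    generator with controllable block-covariance network structure, motion
    spikes and planted pain associations, so the full pipeline is testable
    without access to scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    RNifti,
    yaml,
    optparse
Config/testthat/edition: 3
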