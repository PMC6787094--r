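Package: consdyn
Title: Dynamic Functional Connectivity, Brain States and Entropy Metrics for
    Consciousness Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising consciousness-related changes in brain
    integration and functional diversity from resting-state fMRI: voxelwise
    sample entropy and intrinsic connectivity contrast maps, tapered
    sliding-window dynamic functional connectivity, signed Louvain modularity
    with cartographic profiling (participation coefficient and within-module
    z-score), k-means decomposition of windows into integrated and segregated
    states, state-specific weighted graph metrics with degree-preserving
    rewiring nulls and small-worldness, node-wise connectivity entropy, and
    permutation-based group statistics with Benjamini-Hochberg false discovery
    rate control. Includes a synthetic-cohort generator with planted effects
    on entropy, integration and edge weights, and a config-driven pipeline
    running the full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
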