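Package: fcgraph
Title: Weighted Functional Connectome Graph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional connectivity
    networks built from ROI timeseries: Fisher-z correlation matrices,
    proportional density thresholding and density sweeps, weighted graph
    metrics (clustering, transitivity, path length, efficiency,
    assortativity, participation coefficient, small-world indices,
    rich-club curves), strength- and degree-preserving signed null models
    and lattice references, Louvain consensus modularity, AUC-over-threshold
    summaries with Benjamini-Hochberg control, a PCA explained-inertia
    null-reference procedure, behavioral indices (sucrose preference,
    tone-locked freezing epochs, motion summaries), and a synthetic cohort
    generator with planted modular covariance for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    mclust,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
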