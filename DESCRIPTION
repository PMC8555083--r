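Package: topoconn
Title: Graph-Topology Connectome Features and Two-Stage Deep Classification for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds partial-correlation functional connectomes from region-of-interest
    (ROI) time series, binarizes them over a sparsity grid, computes global and nodal
    graph-topology metrics with degree-preserving random null models, integrates each
    metric curve into a threshold-independent feature (area under the curve), and
    classifies subjects with a stacked-autoencoder dimensionality reduction followed by
    a nested cross-validated linear support vector machine, including a label-permutation
    significance test and a backward weight-propagation report of the most discriminative
    (metric, region) features. A seeded synthetic-cohort generator with planted
    precision-matrix group differences makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
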