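Package: sampleCorrNet
Title: Sample Correlation Networks for LC-MS Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sample-sample correlation networks from LC-MS peak-area
    tables and quantifies how network structure across a correlation-threshold
    sweep separates coarse sample categories (e.g. processing stage) from finer
    nested ones (e.g. country of origin). Provides Spearman and Pearson sample
    correlation matrices, thresholded network construction with Cytoscape
    export, edge-similarity curves with weight-permutation null ensembles,
    ideal-network link accuracy, neighbour majority-vote label inference, a
    nested-design synthetic peak-table generator, and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    readxl,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
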