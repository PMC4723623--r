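Package: berrynet
Title: Stage-Resolved Metabolite Correlation Networks for Grape Berry
    Development
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of GC-MS metabolite profiles across grape
    berry development: median normalization and log2 transformation,
    stage-wise ANOVA/Tukey statistics with false-discovery-rate control,
    PCA and hierarchical clustering overviews, and per-cultivar per-stage
    Spearman correlation networks with a matrix-shuffle permutation null.
    Network topology is characterized (density, path lengths, clustering,
    power-law versus exponential degree-distribution selection by AIC) and
    networks are compared through edge-overlap Fisher tests and
    degree-preserving rewiring null models. A synthetic-data generator with
    planted correlation structure supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ape,
    minpack.lm,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metabolomics, Network, GraphAndNetwork, Normalization
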