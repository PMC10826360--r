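Package: rarebench
Title: Benchmarking Sequencing-Depth Normalization for Microbiome Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A seeded simulation framework for measuring how normalization
    strategies for uneven sequencing depth (rarefaction, single subsampling,
    relative abundance, variance-stabilizing transformation, upper-quartile
    log-fold-change scaling, and raw counts) affect downstream microbiome
    analyses. Synthetic two-group OTU communities are generated from a pair of
    overlapping lognormal parent distributions, sampled multinomially at
    realistic, optionally treatment-confounded library sizes, filtered,
    normalized, and scored for clustering accuracy on ecological distance
    matrices (Bray-Curtis, Euclidean, Poisson, UniFrac, top mean squared
    difference), PERMANOVA type-I error and power, and alpha-diversity
    (richness, Shannon) Wilcoxon tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    vegan,
    cluster,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    picante,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cluster.R'
    'depths.R'
    'distance.R'
    'grid.R'
    'io.R'
    'methods.R'
    'normalize.R'
    'parents.R'
    'rarebench-package.R'
    'simulate.R'
    'stats.R'
    'utils.R'
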