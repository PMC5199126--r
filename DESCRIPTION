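Package: batchevol
Title: Serial-Batch Experimental Evolution: Competition Models,
    Individual-Based Simulation and Growth-Curve Phenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models adaptation of budding yeast populations propagated in
    serial-batch (bottleneck-growth-bottleneck) regimes. Provides a
    deterministic two-subpopulation competition model with analytic and
    regression-based selection coefficients from lag and doubling-time
    differences; a genotype-structured individual-based simulator of batch
    evolution with synchronous divisions, per-division mutation and
    hypergeometric bottleneck sampling; pleiotropic genotype-phenotype maps
    with a gamma distribution of fitness effects and diminishing-returns
    epistasis; targeted-locus mutation-rate scans; extraction of lag,
    doubling time and growth efficiency from plate growth curves; and small
    estimators (fluctuation-assay p0 mutation rate, Poisson standing-variant
    probability, variant-trajectory confidence filter). Synthetic-data
    generators make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
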