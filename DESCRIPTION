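Package: DNBdetect
Title: Dynamical Network Biomarker Detection from Time-Course Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects pre-disease states from two-group, time-course gene
    expression data using dynamical network biomarker (DNB) theory. A small
    group of genes approaching a critical transition transiently shows
    inflated variance and strong mutual correlation; DNBdetect selects such
    gene sets by a three-step ranking on standard-deviation ratios and
    correlation gains, scores candidate sets with the average standard
    deviation (I_s) and bias-corrected average correlation strength (I_r)
    across conditions, and assesses robustness by leave-one-out resampling
    and control-group swaps. The package also provides microarray-style
    preprocessing (probe collapsing, trimmed-mean normalization, log2),
    differential expression by fold-change and Welch tests with
    Benjamini-Hochberg control, PCA with permutation-based parallel
    analysis, correlation-based hierarchical clustering, hypergeometric
    gene-set enrichment (classic and conservative DAVID-style forms), and a
    synthetic-data generator with planted DNB modules and known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    graphics,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
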