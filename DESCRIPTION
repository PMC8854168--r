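Package: dnmcross
Title: Cross-Disorder De Novo Mutation Burden and Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for de novo mutations (DNMs) ascertained from
    parent-offspring trios across several neuropsychiatric disorders.
    Implements variant-class burden testing normalized by synonymous counts,
    ascertainment-differential contribution estimates, gamma-Poisson
    (TADA-Denovo style) Bayes factors with Bayesian FDR gene prioritization,
    mutability-weighted permutation tests of cross-disorder gene-set overlap,
    exact conditional disorder-bias tests, and coexpression/PPI network and
    module-enrichment statistics. Includes a synthetic trio-cohort generator
    with known risk-gene truth so every stage can be validated without
    access to curated study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
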