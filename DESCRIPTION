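Package: chemsig
Title: Chemical-Gene Signature Enrichment for Environmental Exposure
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links environmental chemicals to disease-related gene
    expression. Builds chemical-gene-set signatures from curated
    chemical-gene interaction tables (CTD dialect), maps gene annotations
    across species into a shared ortholog-group namespace, selects
    differentially expressed genes with a permutation-based moderated
    d-statistic, scores every signature for over-representation with the
    upper-tail hypergeometric test, estimates q-values by gene
    resampling, and validates ranked chemical predictions against curated
    disease-chemical associations. Ships a fully seeded synthetic-data
    generator so the whole pipeline is testable without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
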