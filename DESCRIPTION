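Package: coremod
Title: Core Module Biomarker Discovery from Multi-Cohort Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pathway-based identification of reproducible disease "core
    module" biomarkers from several case/control gene expression cohorts.
    Provides pathway-activity inference (core-module inference over ranked
    differentially expressed genes, plus condition-responsive-gene, mean,
    median, first-principal-component, log-likelihood-ratio and
    individual-gene comparators), a cross-cohort reproducibility score over
    ranked activities, consensus feature elimination with linear
    classifiers, pairwise inference/validation assembly of the core module,
    hypergeometric gene-set enrichment, hub-gene driver extraction on an
    interaction network, and a synthetic multi-cohort study generator with
    planted driver and passenger signals for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
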