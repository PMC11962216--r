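Package: targetmr
Title: Drug-Target Mendelian Randomization and Pharmacovigilance Signal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking drug-target gene expression to clinical outcomes by
    combining two evidence streams: disproportionality analysis of spontaneous
    adverse-event reports (reporting odds ratios with signal rules) and
    cis-eQTL instrumented two-sample Mendelian randomization. Implements
    instrument selection with LD clumping, allele harmonization, Steiger and
    F-statistic filtering; Wald-ratio, inverse-variance-weighted, MR-Egger,
    weighted-median and weighted-mode estimators with heterogeneity and
    pleiotropy diagnostics; summary-data-based MR with the HEIDI linkage
    heterogeneity test; approximate-Bayes-factor colocalization; and
    inverse-variance meta-analysis across outcome sources. A synthetic-data
    generator produces LD-structured summary statistics and case-report tables
    with known causal structure so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
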