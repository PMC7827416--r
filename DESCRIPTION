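Package: alloexpr
Title: Expression-Pattern Analysis for Synthetic Allopolyploids and Their Diploid Parents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing subgenome-resolved RNA-seq counts from synthetic
    allopolyploids and their diploid parents. Implements negative-binomial exact
    tests for differential expression with Benjamini-Hochberg adjustment,
    twelve-category expression-level-dominance classification, mid-parent-value
    non-additivity tests, homoeolog expression-bias transition analysis,
    CPM-threshold activation and silencing calls, cross-individual gene-set
    reports, trait clustering, and a negative-binomial count simulator with
    planted expression classes for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
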