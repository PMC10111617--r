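Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with a
    two-step mediation decomposition. Reads and harmonizes GWAS summary
    statistics, selects instrumental variables (p-value thresholding, greedy
    LD clumping, instrument-strength F statistics, Steiger directionality
    filtering), estimates causal effects with the Wald ratio,
    inverse-variance-weighted, MR-Egger and weighted-median estimators,
    runs heterogeneity and pleiotropy diagnostics (Cochran's Q, the Egger
    intercept test, MR-PRESSO), and decomposes a total causal effect on a
    binary outcome into mediated and direct components with the proportion
    mediated. Includes a summary-level GWAS simulator with configurable
    pleiotropy, outliers, palindromic variants, linkage-disequilibrium
    blocks and reverse causation, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
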