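Package: chainMR
Title: Two-Sample Mendelian Randomization Along a Causal Chain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization from GWAS summary statistics,
    organised around mediation along an exposure -> mediator -> outcome chain.
    Provides instrument selection (p-value thresholding, greedy LD clumping,
    F-statistic filtering, outcome-association and palindrome exclusion),
    allele harmonization, five univariable estimators (Wald ratio, inverse
    variance weighted, MR-Egger, weighted median, weighted and simple mode),
    a sensitivity suite (Cochran's Q, Egger intercept, MR-PRESSO outlier
    detection, leave-one-out), multivariable MR, two-step mediation
    decomposition, inverse-variance meta-analysis with I-squared, and grouped
    Benjamini-Hochberg correction. A seeded synthetic summary-statistics
    generator simulates the full causal chain so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    knitr,
    rmarkdown
Config/testthat/edition: 3
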