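Package: sigorder
Title: Signature-Based Rank-Sum Ordering and Extreme-Quartile Contrasts
    for Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Orders tumor expression cohorts along a gene-signature axis by
    summing per-gene ranks within each sample (the BreSAT rank-sum
    procedure), contrasts query genes between the extreme quantile groups
    of the ordering with Welch-corrected t-tests, combines independent
    tests with Fisher's method, clusters samples hierarchically over the
    signature, applies cohort eligibility filtering, tallies cross-dataset
    concordance, and simulates synthetic microarray cohorts with planted
    low/medium/high Wnt-activity classes, co-regulated transcription-factor
    genes and an epithelial-mesenchymal transition block for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
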