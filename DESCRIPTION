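Package: hdrscreen
Title: Pooled CRISPR Knock-In Screening Statistics and Gene Conversion
    Tract Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of pooled CRISPR/Cas9 knock-in
    (homology-directed repair) screens of the kind used in mosquito
    transgenesis. Computes minimum integration rates and exact binomial
    construct comparisons, estimates the underlying per-founder
    integration rate from pooled cross positivity via a group-testing
    likelihood with exact and profile compatibility intervals, classifies
    gene conversion tracts from donor SNP calls (direction, censored
    extents, continuity, repair-mechanism label), and ships a synthetic
    experiment generator so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
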