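Package: abprio
Title: Cross-Species Gene Prioritization for Amyloid-Beta Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Integrates a two-step mouse hippocampal expression screen with
    gene-based statistics from a human case-control genome-wide association
    study to prioritize genes that modulate amyloid-beta accumulation.
    Implements strain-differential and amyloid-correlation screening,
    covariate-adjusted per-SNP logistic association with genomic-inflation
    diagnostics, LD-aware SNP-to-gene assignment, the extended-Simes (GATES)
    gene-based test with an effective number of independent tests,
    unweighted inverse-normal (Stouffer) combination of the two evidence
    streams, a reference-gene-normalized expression validation stage, and a
    seeded synthetic-data generator for end-to-end calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
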