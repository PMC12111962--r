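Package: oncocohort
Title: Comparative Cancer Cohort Genomics: Germline Filtering, Mutational
    Signatures and Driver-Gene Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for contrasting the genomic landscape of a
    small tumor cohort against a large reference cohort from whole-exome
    variant tables. Implements an ACMG-style germline variant prioritization
    cascade with a two-of-three in-silico rescue of variants of uncertain
    significance; SBS-96 mutational-signature catalog construction and
    exposure refitting by non-negative least squares with mean-of-proportions
    cohort summaries; a bootstrap consensus framework for driver-gene
    candidacy (top-decile extraction, two-of-three joint detection, empirical
    nulls for multi-tool coincidence and cross-cohort overlap, and a
    subsample test for sample-size bias); per-gene somatic frequency
    comparisons and tumor mutational burden. A synthetic-cohort generator
    with planted ground truth (signature mixtures, driver genes, germline
    carriers, tunably concordant ranking tables) makes the full pipeline
    testable without access to any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
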