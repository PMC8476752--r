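Package: icpScore
Title: Immune Cell Pair Scores for Prognostic Modelling from Bulk Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates Immune Cell Pair (ICP) prognostic signatures
    from bulk gene-expression cohorts. Per-sample immune-cell enrichment is
    estimated by single-sample gene set enrichment analysis (ssGSEA) over
    marker gene sets; within-sample binary comparisons of enrichment between
    cell-type pairs yield platform-robust pair indicators; pairs are selected
    by Cox regression and Harrell's concordance index, summed into an integer
    ICP score, and dichotomized at a maximally selected log-rank cutpoint.
    Includes from-scratch survival statistics (Cox partial likelihood with
    Efron/Breslow ties, Kaplan-Meier, log-rank, time-dependent AUC with
    inverse-probability-of-censoring weights), GMT signature handling, a
    multi-cohort synthetic-data generator with known ground truth, and
    file-based pipeline orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
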