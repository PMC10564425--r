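Package: ferroscore
Title: Ferroptosis Potential Index Scoring and Immune-Survival Analysis for
    Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-sample ferroptosis potential indices (FPI) from
    single-sample gene-set enrichment of positive and negative ferroptosis
    regulator genes, stratifies cohorts at a maximally selected log-rank
    cutpoint, scores immune-cell infiltration from marker gene sets and
    quantifies its association with the FPI, and performs empirical-Bayes
    moderated differential analysis of genes and per-sample pathway scores.
    Ships from-scratch ssGSEA, GSVA-style and permutation GSEA engines, a
    Kaplan-Meier/log-rank/chi-square statistics layer, a single-cell QC
    filter, and a seeded synthetic cohort generator that plants latent
    ferroptosis activity in expression, immune marker blocks and survival so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
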