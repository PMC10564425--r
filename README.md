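# ferroscore

Ferroptosis potential index (FPI) scoring and immune–survival analysis for
bulk transcriptomes.

## The problem

Ferroptosis — iron-dependent, lipid-peroxidation-driven cell death — is
linked to tumor progression and to the immune microenvironment in lung
adenocarcinoma and other cancers. A practical way to quantify it from bulk
RNA expression is a per-sample **ferroptosis potential index**:

```
FPI_j = ES_j(positive regulators) − ES_j(negative regulators)
```

where `ES_j(S)` is the single-sample GSEA (ssGSEA) enrichment score of the
ferroptosis-regulator gene set `S` in sample `j`. Once every sample carries
an FPI, the downstream questions are standard but fiddly to wire together:

- does the FPI stratify overall survival? (maximally selected log-rank
  cutpoint, Kaplan–Meier curves, log-rank test)
- which immune cell populations track ferroptosis activity? (ssGSEA over
  marker gene sets, then plain or partial Pearson correlation with the FPI,
  Benjamini–Hochberg adjusted)
- which genes and pathways differ between FPI-high and FPI-low patients?
  (empirical-Bayes moderated t on the expression matrix and on per-sample
  GSVA pathway scores; selection at |log2FC| ≥ 1.5 and BH-adjusted
  p < 0.05)
- do dichotomized biomarkers associate with clinicopathologic features?
  (Pearson chi-square on contingency tables)

`ferroscore` implements this whole pipeline for analysts working with
gene × sample expression matrices (TSV/CSV), GMT gene sets, and TSV sample
annotations. The enrichment engines (ssGSEA, GSVA-style kernel-CDF
scoring, permutation GSEA), the Kaplan–Meier/log-rank layer, the
maximally selected cutpoint, the moderated t, and the partial-correlation
machinery are implemented in the package and validated against independent
brute-force oracles and, where available, against the `survival` and
`limma` packages.

Because the motivating cohorts (TCGA bulk expression, GEO single-cell
data) are external, the package ships a **synthetic cohort generator**
that plants the assumed signal structure — a latent per-sample ferroptosis
activity driving regulator genes in opposite directions, immune marker
blocks correlated with it (B cells strongest), and exponential survival
whose hazard falls with ferroptosis activity — so every stage is testable
end to end with no downloads.

## Worked example

```r
library(ferroscore)

cfg <- pipeline_config(
  simulation = cohort_config(n_samples = 120, n_background_genes = 150,
                             seed = 7))
bundle <- run_pipeline(cfg)
cat(make_report(bundle))
```

prints

```
# FPI pipeline report

- Samples: 120, genes: 358
- FPI cutoff (maximally selected log-rank): 0.4374 over 97 candidates
- Log-rank high vs low FPI: chisq = 16.742, p = 4.28e-05
- Worse-survival group: low FPI

## FPI-correlated immune cell types (descending |r|)
- B_cells: r = 0.776 (padj = 4.95e-24)
- CD8_T_cells: r = 0.687 (padj = 5.54e-17)
- NK_CD56bright_cells: r = 0.539 (padj = 1.68e-09)
...
```

Reading this: the pipeline scored the two ferroptosis-regulator sets per
sample, took their difference as the FPI, min–max standardized it to
[0, 1], and found the FPI threshold (0.4374) that maximizes the two-group
log-rank statistic while keeping both groups at ≥ 10% of the cohort. The
FPI-low group has significantly worse survival (p ≈ 4e-05), matching the
planted hazard direction; B cells show the strongest FPI association,
matching the planted correlation ordering. The differential section lists
genes and GSVA pathway scores passing the |effect| / FDR selection rule.

The same pipeline runs on real files:

```r
cfg <- pipeline_config(
  expression  = "expr.tsv",      # genes x samples, log2 scale
  annotations = "ann.tsv",       # sample_id, group, time, event
  frg_gmt     = "frg.gmt",       # FRG_positive / FRG_negative sets
  marker_gmt  = "immune_markers.gmt",
  out_dir     = "results/")
run_pipeline(cfg)
```

A starter GMT with the printed ferroptosis-regulator panel (12 positive,
4 named negative regulators — a documented partial list, not the full
24-gene panel) ships in `inst/extdata/frg_starter.gmt`; the immune marker
GMT there is a synthetic fixture for testing, not a curated human marker
panel.

Individual stages are exported if you want only a piece:
`ssgsea_scores()`, `gsva_scores()`, `gsea_two_group()`, `compute_fpi()`,
`standardize_fpi()`, `optimal_cutpoint()`, `km_estimate()`,
`logrank_test()`, `chisq_independence()`, `infiltration_scores()`,
`correlate_fpi_infiltration()`, `moderated_t_test()`,
`qc_filter_cells()` (single-cell QC at min 500 / max 4000 detected genes
and < 5% mitochondrial counts), and the generators `generate_cohort()` /
`generate_toy_survival()`.

Chi-square on a dichotomized biomarker, e.g. WDFY4-high vs -low by tumor
location from the shipped contingency counts:

```r
chisq_independence(wdfy4_table1()$tumor_location)
#> <chisq> X2 = 4.90928 on 1 df, p = 0.02671
```

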