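---
title: "Methods: FPI scoring, survival stratification, and immune correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FPI scoring, survival stratification, and immune correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroscore)
```

This vignette documents the statistical machinery in `ferroscore`, the
assumptions behind each stage, the defaults and why they were chosen, and
what the synthetic cohort generator does and does not emulate.

## The ferroptosis potential index

For a log2-scale expression matrix $X$ (genes $\times$ samples) and two
gene sets of ferroptosis regulators — positive (pro-ferroptotic) and
negative (anti-ferroptotic) — the FPI of sample $j$ is

$$\mathrm{FPI}_j = ES_j(\text{positive}) - ES_j(\text{negative}),$$

with $ES_j$ the ssGSEA enrichment score. ssGSEA ranks the genes of one
sample in descending expression order and walks down the list: in-set
genes accumulate their descending rank raised to $\alpha$, normalized so
the in-set mass ends at 1; out-of-set genes accumulate uniformly. The
score is the sum of the running deviation over all positions. Because
only ranks enter, any strictly monotone transform of a sample's values
leaves its scores unchanged — which also means FPI is insensitive to
whether the input was TPM, FPKM, or counts, *provided the caller logged
it consistently*; the `scale_tag` on `expression_matrix()` forces that
declaration rather than guessing.

Key parameters:

- `alpha = 0.25` — the original ssGSEA weight exponent; the method the
  index is built on names ssGSEA without parameters, so the canonical
  default is used.
- `normalize = TRUE` — all scores divided by the global (max − min) over
  the score matrix, the usual "ssGSEA normalization". Normalization is a
  single positive rescaling, so FPI ordering is unchanged by it.

The shipped regulator panel (`frg_sets()`, and
`inst/extdata/frg_starter.gmt`) carries the 12 printed positive
regulators (LPCAT3, NCOA4, ACSL4, GPX4, SLC3A2, ALOX15, SLC7A11, NOX5,
NFE2L2, NOX3, NOX1, NOX4) and the 4 printed negative regulators (FDFT1,
COQ10A, HMGCR, COQ10B). The source list is explicitly partial ("among
others"), so the fixture is a starter, not a claimed-complete 24-gene
panel; real analyses should supply a curated GMT. Note GPX4, SLC7A11 and
NFE2L2 sit in the positive set as printed, although canonically they
*suppress* ferroptosis; the fixture follows the printed panel verbatim
and this discrepancy is deliberately not "corrected".

**Standardization.** `standardize_fpi()` min–max rescales to $[0,1]$.
Min–max was chosen over z-scoring because the published survival
threshold convention (a cutoff like 0.47 on an apparently bounded scale,
with "FPI < cutoff" defining the better-survival group) only makes sense
on a [0, 1] scale; this is an assumption, flagged here. The pipeline
standardizes *before* cutpoint selection — the alternative order is not
distinguishable from the published description, and since min–max is
strictly monotone the selected *partition* of samples is identical either
way; only the printed cutoff value changes scale.

**Grouping.** `assign_groups()` labels `fpi < cutoff` as "low", everything
else "high". A sample exactly at the cutoff is "high", matching the
strict inequality in the convention above.

## Survival machinery

`km_estimate()` is the product-limit estimator over distinct event times;
`logrank_test()` the standard two-group observed-minus-expected
chi-square on 1 df, computed in one $O(n\log n)$ pass so that
`optimal_cutpoint()` can afford to evaluate every candidate split. Both
are validated against hand tabulations and against the `survival`
package in the test suite.

`optimal_cutpoint()` scans every observed score value whose
`low = score < value` split keeps both groups at `minprop` of the cohort
or more, and returns the split maximizing the log-rank statistic (ties
toward the smaller cutoff, deterministically).

- `minprop = 0.10` — the convention of the cutpoint tooling the approach
  is named after (survminer-style maximally selected statistics).
- **No multiplicity correction** is applied to the cutpoint's p-value:
  the source analysis reports none, and silently correcting would make
  results incomparable. Instead `candidates_evaluated` is returned so
  users can apply their own correction; the reported p should otherwise
  be read as descriptive, since maximal selection inflates it badly.

`chisq_independence()` is the Pearson chi-square **without continuity
correction** (wrapping `stats::chisq.test(correct = FALSE)`). That
convention reproduces, to printed precision, the published p-values for
the WDFY4 contingency tables shipped in `wdfy4_table1()` (tumor location
0.0267, tumor size 0.7931, lymph node 0.8378, TNM stage 0.217, grade
0.6007). Two printed rows are *not* reproducible from their counts under
any standard chi-square variant (the age row, printed 0.3280 vs 0.7846
computed, and the gender row, whose printed percentages are internally
inconsistent); they are kept in the fixture for completeness, documented,
and excluded from validation rather than guessed at.

## GSVA-style pathway scores

`gsva_scores()` transforms each gene's expression to a cross-sample
cumulative statistic via a kernel CDF, ranks those statistics per sample,
folds the ranks into a statistic symmetric about the mid-rank, and runs a
weighted KS-like walk per set.

- `kcdf = "gaussian"` with bandwidth $s_i/4$ (per-gene SD over samples)
  for log-scale data; `"poisson"` for counts; `"none"` for the empirical
  CDF. All three are exposed because the single-cell variant of the
  analysis names the method without stating the kernel; none is asserted
  as "the" published choice.
- `tau = 1`, `max_diff = TRUE` (score = largest positive plus largest
  negative deviation) — the published GSVA defaults.
- At least 4 samples are required: with fewer, the cross-sample kernel
  estimate is meaningless.

An important consequence of the cross-sample CDF: GSVA scores are
*relative across samples*. A set of genes that is highly expressed in
every sample is **not** positively enriched everywhere — only samples
where the set sits high against each gene's own cross-sample distribution
score positive. The tests assert exactly this relative form.

## Two-group GSEA

`gsea_two_group()` ranks genes by signal-to-noise
$(\mu_1-\mu_0)/(s_1+s_0)$, scores each set by a weighted KS walk (weight
exponent 1, signed maximum deviation), and builds the null by permuting
sample labels. The p-value is two-sided over all permutations,
$p = (1 + \#\{|ES^\ast| \ge |ES|\})/(B+1)$, which matches an exhaustive
enumeration oracle at small $n$ in the tests; NES divides ES by the mean
|null ES| of matching sign. Set-size bounds default to
`min_size = 10`, `max_size = 500`, and excluded sets are reported, not
silently dropped. The permutation seed is a mandatory argument — there is
no hidden global randomness anywhere in the package.

## Moderated differential analysis

`moderated_t_test()` is an empirical-Bayes two-sample t: effects are the
raw difference of class means (never shrunk); per-feature variances are
shrunk toward a prior $(d_0, s_0^2)$ fitted by moment-matching the log
sample variances to a scaled F distribution (digamma/trigamma moments;
the trigamma inverse is solved by bisection to 1e-8). The moderated t has
$d_0 + d$ degrees of freedom. Edge conventions:

- no excess spread in the log variances ⇒ $d_0 = \infty$ and
  $s_0^2$ = mean of the sample variances (the same convention as limma's
  fit, against which the whole path is cross-checked in the tests);
- a degenerate fit falls back to $d_0 = 0$, the ordinary t, with a
  warning;
- `d0 = 0` reproduces the classical equal-variance t exactly.

`select_features()` applies the published rule, read two-sidedly:
$|\text{effect}| \ge 1.5$ (log2 units for genes) **and** BH-adjusted
$p < 0.05$. Two deliberate interpretations, both flagged as assumptions:
"log2 fold change ≥ 1.5" is taken literally as a threshold on the log2
scale (not ratio ≥ 1.5, i.e. log2FC ≥ 0.585 — the threshold is an
argument, so either reading is one keystroke away), and the absolute
value is used because both up- and down-regulated features are reported
downstream. For pathway score matrices the machinery is identical but the
default threshold is 0.1, because GSVA scores are bounded deviations, not
log ratios.

## Immune infiltration and correlation

`infiltration_scores()` is ssGSEA over one marker set per immune cell
type — relative enrichment, not proportion deconvolution. The published
analysis uses 24 cell types with marker sets it does not enumerate
(citing a published marker compendium); the package therefore treats
markers as a required GMT input and ships a clearly-synthetic fixture
(`synthetic_immune_marker_sets()`, generated gene ids) for testing only.

`correlate_fpi_infiltration()` z-standardizes each cell type's scores and
computes Pearson correlation with the FPI; the published description
("bias correlation … adjusted by Pearson's method") is ambiguous, and is
read here as: *partial* Pearson correlation when confounders are
supplied, plain Pearson otherwise. Both paths are explicit; with no
controls they coincide exactly (tested). The partial correlation uses the
recursive first-order formula, which the tests verify against the
residual-regression identity. p-values are two-sided t approximations on
$n-2-k$ df, BH-adjusted across cell types. No default confounder is
imposed, since none is stated in the source analysis.

## Single-cell QC filter

`qc_filter_cells()` applies the published thresholds as strict generic
filters on a counts matrix: detected genes in $[500, 4000]$ (inclusive)
and mitochondrial count fraction strictly below 5% (a cell at exactly
0.05 is removed, per the printed strict inequality). Failure reasons are
tallied independently, so a cell can appear in several counters. No
clustering, annotation, or pseudotime machinery is included — the filter
is the only single-cell stage in scope.

## The synthetic cohort generator

`generate_cohort()` plants the signal structure the analysis assumes,
with one latent ferroptosis activity $f_j \sim N(\text{shift}_g, 1)$ per
sample:

- positive/negative FRG rows get mean shifts $\pm\gamma f_j$ (log2
  units), default $\gamma = 1$;
- each immune cell type's marker genes are
  $\rho_c f_j + \sqrt{1-\rho_c^2}\,\varepsilon$, scaled by `noise_sd`, so
  the *gene-level* correlation with $f$ is $\rho_c$ by construction.
  Default ordering: B cells 0.60, CD8 T 0.45, T helper 0.40, Th17 0.35,
  NK CD56bright 0.30, NK CD56dim 0.25, all other types 0.10 — encoding
  the qualitative claims the pipeline must recover (B cells strongest,
  the named six significant) without pretending to estimate real effect
  sizes, which the source does not report;
- survival is exponential with rate
  $h_0 e^{-\beta f_j}$ ($\beta = 0.5$, $h_0 = 10^{-3}$/day), censored at
  $U(0, 3000)$ days — so higher ferroptosis activity means longer
  survival, the direction the pipeline must find;
- tumor samples get a latent shift of $-0.5$ (tumors less ferroptotic),
  normals 0; background genes are pure noise.

Exponential survival (rather than Weibull) keeps the hazard in closed
form; uniform censoring is independent of everything. All randomness
flows from a single seed, and the simulated latent factor is kept in the
annotations (`latent_ferroptosis`) so recovery can be measured.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: single-cell count sparsity,
batch effects, tumor purity, correlated gene–gene noise beyond the
planted blocks, non-proportional hazards, and informative censoring.
Effect sizes are free parameters documented here, not estimates of any
cohort.

## Validation strategy and problem sizes

Every engine is tested against an independent oracle implemented as a
literal loop in the test suite: ssGSEA and GSVA against brute-force walk
summations (agreement to 1e-12 on ≤ 6-gene fixtures), GSEA permutation
p-values against exhaustive enumeration of all 70 labelings at $n = 8$
(within 3 Monte-Carlo standard errors), KM/log-rank against hand
tabulations and the `survival` package, the moderated t against `limma`,
the cutpoint against a brute-force scan at $n = 50$. Simulation checks
use the sizes at which the planted effects are comfortably identifiable:
cutpoint recovery of a planted step hazard at $n = 500$ over 100
replicates (±0.05 in ≥ 90%), correlation-ordering recovery at $n = 500$
over 200 replicates (≥ 95%), log-rank type-I error over 1000 null
replicates, GSEA type-I error over 200 null datasets, and moderated-t
p-uniformity at 2000 features. Numerical tie-breaks are deterministic
throughout: exact expression ties in walk order break by gene id, GSVA
CDF ranks use average ranks, cutpoint ties go to the smaller threshold.

## Known limitations

- The FPI depends on the regulator panel; the shipped starter panel is
  partial by construction.
- The cutpoint p-value is maximally selected and uncorrected (see above).
- Infiltration scores are relative enrichment; they cannot be compared
  across cell types or interpreted as proportions.
- The moderated test supports two groups only — no covariates, trends, or
  precision weights.
- GSVA kernels assume either roughly continuous log-scale data (gaussian)
  or counts (poisson); mixed-scale matrices are the caller's
  responsibility to avoid.
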