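#' Single-cell quality-control filter
#'
#' Keeps cells (columns of a count matrix) whose detected-gene count lies in
#' `[min_genes, max_genes]` and whose mitochondrial count fraction is
#' strictly below `mito_max`. A cell can fail several criteria; the report
#' tallies every reason independently, so the failure counts can exceed
#' `cells_in - cells_out`.
#'
#' @param expr an [expression_matrix()] with `scale_tag = "counts"`,
#'   non-negative values; mitochondrial genes are identified by id prefix.
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @param min_genes,max_genes detected-gene bounds (inclusive).
#' @param mito_max strict upper bound on the mitochondrial count fraction.
#' @return list with `expr` (filtered matrix) and `report` (class
#'   `"qc_report"`: `cells_in`, `cells_out`, `failed_min_genes`,
#'   `failed_max_genes`, `failed_mito`).
#' @export
qc_filter_cells <- function(expr, mito_prefix = "MT-", min_genes = 500,
                            max_genes = 4000, mito_max = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (attr(expr, "scale_tag") != "counts")
    stop("qc_filter_cells expects a counts-scale matrix", call. = FALSE)
  m <- unclass(expr)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  detected <- colSums(m > 0)
  mito <- startsWith(rownames(m), mito_prefix)
  total <- colSums(m)
  mito_frac <- ifelse(total > 0, colSums(m[mito, , drop = FALSE]) / total, 0)
  fail_min <- detected < min_genes
  fail_max <- detected > max_genes
  fail_mito <- mito_frac >= mito_max
  keep <- !(fail_min | fail_max | fail_mito)
  report <- structure(list(cells_in = ncol(m), cells_out = sum(keep),
                           failed_min_genes = sum(fail_min),
                           failed_max_genes = sum(fail_max),
                           failed_mito = sum(fail_mito)),
                      class = "qc_report")
  if (!any(keep)) {
    e <- simpleError("no cells pass QC")
    e$report <- report
    stop(e)
  }
  list(expr = expression_matrix(m[, keep, drop = FALSE], "counts"),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d -> %d cells ",
                     "(min_genes fail %d, max_genes fail %d, mito fail %d)\n"),
              x$cells_in, x$cells_out, x$failed_min_genes,
              x$failed_max_genes, x$failed_mito))
  invisible(x)
}

#' Pipeline configuration
#'
#' Full-analysis configuration. Exactly one input source must be given:
#' either the three real-input paths (`expression`, `annotations`,
#' `frg_gmt`) or a `simulation` block ([cohort_config()]). Every analysis
#' threshold is a named key with the conventional default.
#'
#' @param expression,annotations,frg_gmt,marker_gmt,pathway_gmt input file
#'   paths (real-data mode). `marker_gmt` / `pathway_gmt` optional; the
#'   pathway collection defaults to the FRG + marker sets.
#' @param simulation a [cohort_config()] (simulation mode).
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param gsva_kcdf,gsva_tau,gsva_max_diff GSVA options.
#' @param minprop minimum group proportion for the survival cutpoint.
#' @param effect_threshold gene-level |log2FC| selection threshold.
#' @param pathway_effect_threshold pathway-score difference threshold
#'   (GSVA scores are not log ratios, so the gene default does not apply).
#' @param alpha B-H adjusted p-value cutoff.
#' @param min_size,max_size gene-set size bounds for enrichment.
#' @param seed root seed for any stochastic stage.
#' @param out_dir optional output directory; when set, every intermediate
#'   table, a JSON summary and a run log are written there.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression = NULL, annotations = NULL,
                            frg_gmt = NULL, marker_gmt = NULL,
                            pathway_gmt = NULL, simulation = NULL,
                            ssgsea_alpha = 0.25,
                            gsva_kcdf = "gaussian", gsva_tau = 1,
                            gsva_max_diff = TRUE, minprop = 0.10,
                            effect_threshold = 1.5,
                            pathway_effect_threshold = 0.10,
                            alpha = 0.05, min_size = 10, max_size = 500,
                            seed = 1, out_dir = NULL) {
  real <- !is.null(expression) || !is.null(annotations) || !is.null(frg_gmt)
  sim <- !is.null(simulation)
  if (real == sim)
    stop("give exactly one of {expression/annotations/frg_gmt paths, ",
         "simulation block}", call. = FALSE)
  if (real && (is.null(expression) || is.null(annotations) || is.null(frg_gmt)))
    stop("real-input mode needs `expression`, `annotations` and `frg_gmt`",
         call. = FALSE)
  if (sim && !inherits(simulation, "cohort_config"))
    stop("`simulation` must be a cohort_config()", call. = FALSE)
  stopifnot(ssgsea_alpha >= 0, minprop > 0, minprop < 0.5,
            alpha > 0, alpha < 1, min_size >= 1, max_size >= min_size)
  cfg <- list(expression = expression, annotations = annotations,
              frg_gmt = frg_gmt, marker_gmt = marker_gmt,
              pathway_gmt = pathway_gmt, simulation = simulation,
              ssgsea_alpha = ssgsea_alpha, gsva_kcdf = gsva_kcdf,
              gsva_tau = gsva_tau, gsva_max_diff = gsva_max_diff,
              minprop = minprop, effect_threshold = effect_threshold,
              pathway_effect_threshold = pathway_effect_threshold,
              alpha = alpha, min_size = min_size, max_size = max_size,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a `simulation`
#' mapping maps to [cohort_config()] arguments (`rho_by_celltype` as a
#' named mapping).
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    sim <- y$simulation
    if (!is.null(sim$rho_by_celltype))
      sim$rho_by_celltype <- unlist(sim$rho_by_celltype)
    y$simulation <- do.call(cohort_config, sim)
  }
  do.call(pipeline_config, y)
}

# restricted mean survival time: area under the KM step function on [0, tau]
km_rmst <- function(curve, tau) {
  tt <- c(0, curve$times[curve$times <= tau], tau)
  ss <- c(1, curve$survival[curve$times <= tau])
  sum(diff(tt) * ss)
}

pipeline_stage <- function(name, expr_) {
  tryCatch(expr_, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full FPI analysis pipeline
#'
#' Executes: input (simulate or load) -> ssGSEA FRG scores -> FPI ->
#' min-max standardization -> maximally selected survival cutpoint ->
#' high/low grouping -> moderated-t DEGs between FPI groups -> immune
#' infiltration scores and FPI correlations -> GSVA pathway scores ->
#' pathway differential analysis -> per-group KM curves and log-rank test.
#' All randomness flows from the config seed; two runs with the same
#' config produce identical outputs. With `out_dir` set, every
#' intermediate table is written as TSV plus a JSON summary and run log.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"ferro_bundle"` with elements `fpi`, `cutpoint`,
#'   `degs`, `infiltration`, `correlations`, `edges`, `pathway_scores`,
#'   `pathway_diff`, `km`, `logrank`, `summary`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  logf <- function(...) {
    line <- paste0(format(c(...), digits = 6), collapse = "")
    log_lines <<- c(log_lines, line)
    message(line)
  }

  if (!is.null(config$simulation)) {
    logf("stage input: simulating cohort, seed = ", config$simulation$seed)
    sim <- pipeline_stage("input", generate_cohort(config$simulation))
    expr <- sim$expr; ann <- sim$ann
    frg <- sim$sets[c("FRG_positive", "FRG_negative")]
    markers <- sim$sets[setdiff(names(sim$sets),
                                c("FRG_positive", "FRG_negative"))]
    pathways <- sim$sets
  } else {
    logf("stage input: loading ", config$expression)
    expr <- pipeline_stage("input", read_expression(config$expression))
    ann <- pipeline_stage("input", read_annotations(config$annotations))
    al <- pipeline_stage("input", align_cohort(expr, ann))
    expr <- al$expr; ann <- al$ann
    frg <- pipeline_stage("input", read_gmt(config$frg_gmt))
    markers <- if (!is.null(config$marker_gmt))
      pipeline_stage("input", read_gmt(config$marker_gmt)) else NULL
    pathways <- if (!is.null(config$pathway_gmt))
      pipeline_stage("input", read_gmt(config$pathway_gmt)) else frg
  }
  logf("input: ", nrow(expr), " genes x ", ncol(expr), " samples")

  logf("stage frg_scores: ssGSEA alpha = ", config$ssgsea_alpha)
  frg_scores <- pipeline_stage("frg_scores",
    ssgsea_scores(expr, frg, alpha = config$ssgsea_alpha))

  fpi <- pipeline_stage("fpi", {
    standardize_fpi(compute_fpi(frg_scores,
                                positive = names(frg)[1L],
                                negative = names(frg)[2L]))
  })
  logf("stage fpi: standardized (min-max), range 0..1")

  cut <- pipeline_stage("cutpoint", {
    v <- stats::setNames(fpi$fpi, fpi$sample_id)
    optimal_cutpoint(v, ann, minprop = config$minprop)
  })
  logf("stage cutpoint: cutoff = ", cut$cutoff, " over ",
       cut$candidates_evaluated, " candidates")
  fpi <- pipeline_stage("cutpoint", assign_groups(fpi, cut$cutoff))

  grp_ann <- ann
  grp_ann$group <- fpi$group[match(ann$sample_id, fpi$sample_id)]
  grp_ann <- cohort_annotations(as.data.frame(grp_ann))

  degs <- pipeline_stage("degs", {
    res <- moderated_t_test(expr, factor(fpi$group, levels = c("low", "high")))
    suppressMessages(select_features(res, config$effect_threshold,
                                     config$alpha))
  })
  logf("stage degs: ", sum(degs$selected), " selected of ", nrow(degs))

  infil <- correlations <- edges <- NULL
  if (!is.null(markers) && length(markers)) {
    infil <- pipeline_stage("infiltration",
      infiltration_scores(expr, markers, alpha = config$ssgsea_alpha))
    correlations <- pipeline_stage("correlations",
      correlate_fpi_infiltration(fpi, infil))
    edges <- network_edges(correlations, config$alpha)
    logf("stage immune: ", nrow(infil), " cell types, ",
         nrow(edges), " significant edges")
  }

  pw_scores <- pipeline_stage("pathway_scores",
    gsva_scores(expr, pathways, tau = config$gsva_tau,
                max_diff = config$gsva_max_diff, kcdf = config$gsva_kcdf))
  pw_diff <- pipeline_stage("pathway_diff", {
    res <- moderated_t_test(pw_scores,
                            factor(fpi$group, levels = c("low", "high")))
    suppressMessages(select_features(res, config$pathway_effect_threshold,
                                     config$alpha))
  })
  logf("stage pathways: ", sum(pw_diff$selected), " selected of ",
       nrow(pw_diff))

  km <- pipeline_stage("survival", {
    list(low = km_estimate(grp_ann, "low"), high = km_estimate(grp_ann, "high"))
  })
  lr <- pipeline_stage("survival", logrank_test(grp_ann, c("low", "high")))
  tau <- min(max(grp_ann$time[grp_ann$group == "low"]),
             max(grp_ann$time[grp_ann$group == "high"]))
  rmst <- c(low = km_rmst(km$low, tau), high = km_rmst(km$high, tau))
  worse <- names(rmst)[which.min(rmst)]
  logf("stage survival: log-rank p = ", lr$pvalue, ", worse group = ", worse)

  top_cor <- if (!is.null(correlations)) {
    oc <- correlations[order(-abs(correlations$r)), ]
    utils::head(oc, 5L)
  } else NULL

  summary <- list(
    n_samples = ncol(expr), n_genes = nrow(expr),
    fpi_cutoff = cut$cutoff,
    cutpoint_statistic = cut$statistic,
    cutpoint_candidates = cut$candidates_evaluated,
    logrank_statistic = lr$statistic, logrank_p = lr$pvalue,
    worse_survival_group = worse,
    rmst = as.list(rmst),
    n_deg_selected = sum(degs$selected),
    n_pathways_selected = sum(pw_diff$selected),
    top_cell_types = if (!is.null(top_cor))
      lapply(seq_len(nrow(top_cor)), function(i)
        list(cell_type = top_cor$cell_type[i], r = top_cor$r[i],
             padj = top_cor$padj[i])) else list(),
    parameters = config[c("ssgsea_alpha", "gsva_kcdf", "gsva_tau",
                          "minprop", "effect_threshold",
                          "pathway_effect_threshold", "alpha",
                          "min_size", "max_size", "seed")])

  bundle <- list(fpi = fpi, cutpoint = cut, degs = degs,
                 infiltration = infil, correlations = correlations,
                 edges = edges, pathway_scores = pw_scores,
                 pathway_diff = pw_diff, km = km, logrank = lr,
                 summary = summary, config = config, log = log_lines)
  class(bundle) <- "ferro_bundle"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.table(x, file.path(config$out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
    w(as.data.frame(fpi), "fpi.tsv")
    w(degs, "degs.tsv")
    if (!is.null(correlations)) w(correlations, "correlations.tsv")
    if (!is.null(edges)) w(edges, "edges.tsv")
    w(pw_diff, "pathway_diff.tsv")
    for (g in names(km))
      w(data.frame(time = km[[g]]$times, survival = km[[g]]$survival,
                   at_risk = km[[g]]$at_risk, events = km[[g]]$events),
        paste0("km_", g, ".tsv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  bundle
}

#' Human-readable pipeline report
#'
#' Deterministic markdown summary of a pipeline bundle: FPI cutoff,
#' log-rank result, strongest FPI-correlated cell types (descending |r|),
#' DEG counts (explicitly zero when nothing passed) and selected pathways.
#'
#' @param bundle a `"ferro_bundle"` from [run_pipeline()].
#' @return character scalar of markdown text.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "ferro_bundle"))
  s <- bundle$summary
  lines <- c(
    "# FPI pipeline report",
    "",
    sprintf("- Samples: %d, genes: %d", s$n_samples, s$n_genes),
    sprintf("- FPI cutoff (maximally selected log-rank): %.4f over %d candidates",
            s$fpi_cutoff, s$cutpoint_candidates),
    sprintf("- Log-rank high vs low FPI: chisq = %.3f, p = %.3g",
            s$logrank_statistic, s$logrank_p),
    sprintf("- Worse-survival group: %s FPI", s$worse_survival_group),
    "",
    "## FPI-correlated immune cell types (descending |r|)")
  if (length(s$top_cell_types)) {
    lines <- c(lines, vapply(s$top_cell_types, function(tc)
      sprintf("- %s: r = %.3f (padj = %.3g)", tc$cell_type, tc$r, tc$padj),
      ""))
  } else {
    lines <- c(lines, "- no infiltration analysis in this run")
  }
  lines <- c(lines, "",
    "## Differential analysis",
    if (s$n_deg_selected == 0)
      "- zero genes selected at the effect/FDR thresholds"
    else sprintf("- %d gene(s) selected", s$n_deg_selected),
    if (s$n_pathways_selected == 0)
      "- zero pathway scores selected"
    else sprintf("- %d pathway score(s) selected", s$n_pathways_selected))
  sel <- bundle$pathway_diff[bundle$pathway_diff$selected, , drop = FALSE]
  if (nrow(sel)) {
    sel <- sel[order(-abs(sel$effect)), ]
    lines <- c(lines, vapply(seq_len(nrow(sel)), function(i)
      sprintf("  - %s: effect = %.3f, padj = %.3g", sel$feature[i],
              sel$effect[i], sel$padj[i]), ""))
  }
  paste(lines, collapse = "\n")
}
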