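#' Immune infiltration scores from marker gene sets
#'
#' Relative infiltration of each immune cell type, scored by ssGSEA over
#' its marker set — one score-matrix row per cell type. This is marker-set
#' enrichment, not proportion deconvolution: scores are comparable across
#' samples within a cell type, not across cell types.
#'
#' @param expr an [expression_matrix()].
#' @param marker_sets a [gene_set_collection()], one set per cell type;
#'   every set must have at least one gene in `expr`.
#' @param alpha,normalize passed to [ssgsea_scores()].
#' @return a [score_matrix()], one row per cell type.
#' @export
infiltration_scores <- function(expr, marker_sets, alpha = 0.25,
                                normalize = TRUE) {
  ssgsea_scores(expr, marker_sets, alpha = alpha, normalize = normalize)
}

# Partial Pearson correlation of x and y given the columns of z, by the
# recursive first-order formula applied control by control.
partial_cor <- function(x, y, z = NULL) {
  if (is.null(z) || NCOL(z) == 0L) return(stats::cor(x, y))
  z <- as.matrix(z)
  k <- ncol(z)
  zk <- z[, k]
  rest <- z[, -k, drop = FALSE]
  rxy <- partial_cor(x, y, rest)
  rxz <- partial_cor(x, zk, rest)
  ryz <- partial_cor(y, zk, rest)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Correlate FPI with immune infiltration
#'
#' Per cell type: Pearson correlation between the FPI and the z-standardized
#' infiltration score, or the partial Pearson correlation controlling for
#' the supplied covariates (computed by the recursive first-order formula;
#' with no controls the two are identical). Two-sided p-values come from the
#' t approximation on n - 2 - k degrees of freedom; Benjamini-Hochberg
#' adjustment is applied across cell types.
#'
#' @param fpi an `"fpi_vector"` from [compute_fpi()].
#' @param infil a [score_matrix()] of infiltration scores.
#' @param controls optional numeric matrix / data.frame of covariates with
#'   one row per sample (named rows matched to sample ids if present).
#' @return data.frame of class `"correlation_table"` with columns
#'   `cell_type`, `r`, `pvalue`, `padj`, `n`, sorted as the input rows.
#' @export
correlate_fpi_infiltration <- function(fpi, infil, controls = NULL) {
  stopifnot(inherits(fpi, "fpi_vector"), inherits(infil, "score_matrix"))
  shared <- intersect(fpi$sample_id, colnames(infil))
  if (length(shared) < 5L)
    stop("need >= 5 shared samples between FPI and infiltration scores",
         call. = FALSE)
  x <- fpi$fpi[match(shared, fpi$sample_id)]
  if (stats::sd(x) == 0) stop("FPI is constant", call. = FALSE)
  m <- unclass(infil)[, shared, drop = FALSE]
  k <- 0L
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    if (!is.null(rownames(controls))) {
      idx <- match(shared, rownames(controls))
      if (anyNA(idx))
        stop("`controls` must cover every shared sample", call. = FALSE)
      controls <- controls[idx, , drop = FALSE]
    } else if (nrow(controls) != length(shared)) {
      stop("`controls` must have one row per shared sample", call. = FALSE)
    }
    if (!is.numeric(controls) || anyNA(controls))
      stop("`controls` must be numeric with no missing values", call. = FALSE)
    k <- ncol(controls)
  }
  n <- length(shared)
  r <- vapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    if (stats::sd(y) == 0)
      stop("constant infiltration scores for cell type '",
           rownames(m)[i], "'", call. = FALSE)
    y <- (y - mean(y)) / stats::sd(y)
    partial_cor(x, y, controls)
  }, 0)
  df <- n - 2L - k
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  pvalue <- 2 * stats::pt(-abs(tstat), df = df)
  res <- data.frame(cell_type = rownames(m), r = r, pvalue = pvalue,
                    padj = bh_adjust(pvalue), n = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("correlation_table", "data.frame")
  res
}

#' Export significant FPI-infiltration associations as network edges
#'
#' @param table a `"correlation_table"` from
#'   [correlate_fpi_infiltration()].
#' @param padj_cutoff keep rows with `padj < padj_cutoff`.
#' @return data.frame with columns `source` ("FPI"), `target` (cell type)
#'   and `weight` (r), sorted by |r| descending.
#' @export
network_edges <- function(table, padj_cutoff = 0.05) {
  stopifnot(inherits(table, "correlation_table") || is.data.frame(table))
  keep <- table[table$padj < padj_cutoff, , drop = FALSE]
  keep <- keep[order(-abs(keep$r), keep$cell_type), , drop = FALSE]
  data.frame(source = rep("FPI", nrow(keep)), target = keep$cell_type,
             weight = keep$r, stringsAsFactors = FALSE, row.names = NULL)
}
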