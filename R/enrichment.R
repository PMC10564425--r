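#' Construct a gene-set score matrix
#'
#' Container for per-sample enrichment scores: sets in rows, samples in
#' columns, with the scoring method recorded.
#'
#' @param scores numeric matrix, sets x samples, with dimnames.
#' @param method_tag `"ssgsea"` or `"gsva"`.
#' @return a matrix of class `"score_matrix"`.
#' @export
score_matrix <- function(scores, method_tag = c("ssgsea", "gsva")) {
  method_tag <- match.arg(method_tag)
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score matrix needs set rownames and sample colnames", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("scores must all be finite", call. = FALSE)
  structure(scores, method_tag = method_tag,
            class = c("score_matrix", class(scores)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d sets x %d samples, method = %s\n",
              nrow(x), ncol(x), attr(x, "method_tag")))
  invisible(x)
}

# Weighted Kolmogorov-Smirnov-style random walk over a ranked gene list.
# `w` are non-negative gene-level weights in walk order, `inset` a logical
# indicator in the same order. P_in accumulates w^tau over in-set genes
# (normalized to end at 1), P_out accumulates uniformly over out-of-set
# genes. `mode` picks the enrichment summary of the deviation v:
#   sum       - integral of the deviation (ssGSEA)
#   maxdiff   - max positive deviation + max negative deviation (GSVA default)
#   signedmax - deviation of largest magnitude (classic GSEA / GSVA alt)
ks_walk <- function(w, inset, tau = 1, mode = c("sum", "maxdiff", "signedmax")) {
  mode <- match.arg(mode)
  n <- length(w)
  m <- sum(inset)
  wt <- ifelse(inset, w^tau, 0)
  denom_in <- sum(wt)
  if (denom_in <= 0) stop("in-set weights sum to zero", call. = FALSE)
  p_in <- cumsum(wt) / denom_in
  p_out <- cumsum(!inset) / (n - m)
  v <- p_in - p_out
  switch(mode,
    sum = sum(v),
    maxdiff = max(c(0, v)) + min(c(0, v)),
    signedmax = v[which.max(abs(v))])
}

# Descending walk order for one sample: highest value first, exact ties
# broken by gene id for determinism.
walk_order <- function(x, ids) order(-x, ids)

check_sets_present <- function(sets, genes, allow_full = FALSE) {
  present <- lapply(sets, intersect, genes)
  n_pres <- lengths(present)
  if (any(n_pres == 0L))
    stop("gene set(s) with no member present in the expression matrix: ",
         paste(names(sets)[n_pres == 0L], collapse = ", "), call. = FALSE)
  if (!allow_full && any(n_pres == length(genes)))
    stop("gene set(s) covering every gene in the matrix (no out-of-set ",
         "genes to walk over): ",
         paste(names(sets)[n_pres == length(genes)], collapse = ", "),
         call. = FALSE)
  present
}

#' Single-sample GSEA (ssGSEA) enrichment scores
#'
#' For each sample, genes are ranked by expression in descending order and a
#' rank-weighted running-sum statistic is accumulated per gene set: in-set
#' genes contribute their descending rank raised to `alpha` (normalized so
#' the in-set accumulator ends at 1), out-of-set genes contribute uniformly.
#' The enrichment score is the sum of the running deviation over all rank
#' positions. Scores depend on ranks only, so any strictly monotone
#' transform of a sample's values leaves them unchanged.
#'
#' @param expr an [expression_matrix()] (log scale expected).
#' @param sets a [gene_set_collection()]; every set must have at least one
#'   member present in `expr` and must not cover all genes.
#' @param alpha rank-weight exponent, >= 0; 0.25 is the original ssGSEA
#'   convention.
#' @param normalize divide all scores by the global score range
#'   (max - min across the whole matrix).
#' @return a [score_matrix()] (sets x samples, `method_tag = "ssgsea"`).
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sets, "gene_set_collection"))
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  genes <- rownames(expr)
  n <- length(genes)
  check_sets_present(sets, genes)
  inset_mask <- vapply(sets, function(s) genes %in% s, logical(n))
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- walk_order(expr[, j], genes)
    w <- as.numeric(n:1)            # descending rank weights
    for (k in seq_along(sets)) {
      out[k, j] <- ks_walk(w, inset_mask[ord, k], tau = alpha, mode = "sum")
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  score_matrix(out, "ssgsea")
}

# Kernel-CDF transform of one gene's expression across samples.
kcdf_transform <- function(x, kcdf) {
  n <- length(x)
  switch(kcdf,
    gaussian = {
      h <- stats::sd(x) / 4
      if (h == 0) return(rep(0, n))
      vapply(x, function(xi) sum(stats::pnorm((xi - x) / h)), 0)
    },
    poisson = vapply(x, function(xi) sum(stats::ppois(xi, lambda = x + 0.5)), 0),
    none = rank(x, ties.method = "average") / n)
}

#' GSVA-style per-sample enrichment scores
#'
#' Per gene, expression is transformed to a cross-sample cumulative
#' statistic through a kernel CDF (`gaussian` with bandwidth sd/4 for
#' log-scale data, `poisson` for counts, `none` for the empirical CDF). The
#' transformed values are ranked per sample (average ranks on ties) and
#' folded into a statistic symmetric around the mid-rank; a weighted
#' KS-like walk down the rank-ordered list yields the per-set score:
#' the sum of the largest positive and largest negative deviation when
#' `max_diff` (the conventional GSVA default), otherwise the signed maximum
#' deviation.
#'
#' @param expr an [expression_matrix()]; at least 4 samples are required for
#'   the cross-sample kernel estimate.
#' @param sets a [gene_set_collection()].
#' @param tau walk weight exponent (default 1).
#' @param max_diff score summary flag, see above.
#' @param kcdf kernel choice: `"gaussian"`, `"poisson"` or `"none"`.
#' @return a [score_matrix()] (`method_tag = "gsva"`).
#' @export
gsva_scores <- function(expr, sets, tau = 1, max_diff = TRUE,
                        kcdf = c("gaussian", "poisson", "none")) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sets, "gene_set_collection"))
  kcdf <- match.arg(kcdf)
  if (ncol(expr) < 4L)
    stop("gsva_scores needs >= 4 samples for the kernel CDF estimate",
         call. = FALSE)
  genes <- rownames(expr)
  n <- length(genes)
  check_sets_present(sets, genes)
  inset_mask <- vapply(sets, function(s) genes %in% s, logical(n))
  z <- t(apply(unclass(expr), 1L, kcdf_transform, kcdf = kcdf))
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  mode <- if (max_diff) "maxdiff" else "signedmax"
  for (j in seq_len(ncol(expr))) {
    rk <- rank(z[, j], ties.method = "average")  # ascending
    dec_rk <- n + 1 - rk                         # 1 = largest statistic
    stat <- abs(n / 2 - dec_rk)                  # symmetric about mid-rank
    ord <- walk_order(z[, j], genes)
    for (k in seq_along(sets)) {
      out[k, j] <- ks_walk(stat[ord], inset_mask[ord, k], tau = tau,
                           mode = mode)
    }
  }
  score_matrix(out, "gsva")
}

# signal-to-noise ranking metric for two classes (class1 - class0);
# row SDs computed from sums of squares so the permutation loop stays cheap
signal_to_noise <- function(m, labels1) {
  x1 <- m[, labels1, drop = FALSE]
  x0 <- m[, !labels1, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  s1 <- sqrt(pmax(rowSums(x1^2) - n1 * mu1^2, 0) / (n1 - 1))
  s0 <- sqrt(pmax(rowSums(x0^2) - n0 * mu0^2, 0) / (n0 - 1))
  denom <- s1 + s0
  denom[denom == 0] <- .Machine$double.eps
  (mu1 - mu0) / denom
}

gsea_es_all <- function(stat, genes, inset_mask) {
  ord <- walk_order(stat, genes)
  w <- abs(stat)[ord]
  vapply(seq_len(ncol(inset_mask)), function(k)
    ks_walk(w, inset_mask[ord, k], tau = 1, mode = "signedmax"), 0)
}

#' Two-group GSEA with label-permutation null
#'
#' Genes are ranked by the signal-to-noise statistic between the two sample
#' classes; each gene set is scored by a weighted KS walk (weight exponent
#' 1, signed maximum deviation). The null distribution comes from
#' permutations of the class labels; the p-value is two-sided,
#' `(1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`, and the normalized
#' enrichment score divides ES by the mean |null ES| of matching sign.
#' Sets whose intersection with the matrix falls outside
#' `[min_size, max_size]` are excluded and reported in the `"excluded"`
#' attribute.
#'
#' @param expr an [expression_matrix()] or [score_matrix()].
#' @param labels vector of two classes, one per sample (the second factor
#'   level / larger value is "class 1", whose up-regulation gives ES > 0).
#' @param sets a [gene_set_collection()].
#' @param min_size,max_size retained set-size bounds after intersecting with
#'   the matrix genes.
#' @param n_perm number of label permutations.
#' @param seed RNG seed (mandatory; no hidden global randomness).
#' @return data.frame with columns `set_name`, `size`, `es`, `nes`,
#'   `pvalue`, `padj`, plus an `"excluded"` attribute naming filtered sets.
#' @export
gsea_two_group <- function(expr, labels, sets, min_size = 10, max_size = 500,
                           n_perm = 1000, seed) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  m <- unclass(expr)
  if (length(labels) != ncol(m))
    stop("`labels` must have one entry per sample", call. = FALSE)
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("`labels` must have exactly two classes", call. = FALSE)
  if (any(table(f) < 3L))
    stop("both label classes need >= 3 samples", call. = FALSE)
  labels1 <- f == levels(f)[2L]
  genes <- rownames(m)
  sizes <- vapply(sets, function(s) length(intersect(s, genes)), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  excluded <- names(sets)[!keep]
  if (!any(keep))
    stop("no gene set within [min_size, max_size] after intersecting with ",
         "the matrix genes", call. = FALSE)
  sets <- sets[keep]
  inset_mask <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  es_obs <- gsea_es_all(signal_to_noise(m, labels1), genes, inset_mask)

  set.seed(seed)
  null_es <- matrix(NA_real_, n_perm, length(sets))
  for (b in seq_len(n_perm)) {
    perm <- sample(labels1)
    null_es[b, ] <- gsea_es_all(signal_to_noise(m, perm), genes, inset_mask)
  }
  pvalue <- vapply(seq_along(sets), function(k)
    (1 + sum(abs(null_es[, k]) >= abs(es_obs[k]))) / (n_perm + 1), 0)
  nes <- vapply(seq_along(sets), function(k) {
    same <- null_es[, k][sign(null_es[, k]) == sign(es_obs[k])]
    if (length(same) == 0L) return(NA_real_)
    es_obs[k] / mean(abs(same))
  }, 0)
  res <- data.frame(set_name = names(sets), size = sizes[keep],
                    es = es_obs, nes = nes, pvalue = pvalue,
                    padj = bh_adjust(pvalue), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "excluded") <- excluded
  res
}

#' Pre-ranked enrichment scores
#'
#' Descriptive ES for each set over a user-supplied ranking statistic
#' (e.g. moderated t or GSVA score differences); same walk as
#' [gsea_two_group()] but without a permutation null, which requires sample
#' labels.
#'
#' @param stat named numeric vector of per-gene statistics.
#' @param sets a [gene_set_collection()].
#' @param min_size,max_size retained set-size bounds.
#' @return data.frame with columns `set_name`, `size`, `es`.
#' @export
gsea_preranked <- function(stat, sets, min_size = 10, max_size = 500) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(names(stat))) stop("`stat` must be named by gene", call. = FALSE)
  genes <- names(stat)
  sizes <- vapply(sets, function(s) length(intersect(s, genes)), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no gene set within size bounds", call. = FALSE)
  sets <- sets[keep]
  inset_mask <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  es <- gsea_es_all(stat, genes, inset_mask)
  data.frame(set_name = names(sets), size = sizes[keep], es = es,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with the package's input contract: every p-value
#' must lie in [0, 1].
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}
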