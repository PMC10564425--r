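# Independent brute-force oracles, written as literal position-by-position
# loops so they share no code path with the package's vectorized engines.

# ssGSEA enrichment score for one sample: explicit walk over every rank
# position, accumulating weighted in-set and uniform out-of-set mass.
oracle_ssgsea_es <- function(x, set_genes, alpha) {
  ord <- order(-x, names(x))
  ids <- names(x)[ord]
  n <- length(x)
  w <- (n:1)^alpha
  inset <- ids %in% set_genes
  denom_in <- sum(w[inset])
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + w[i] / denom_in
    else p_out <- p_out + 1 / (n - sum(inset))
    es <- es + (p_in - p_out)
  }
  es
}

# GSVA score with empirical-CDF kernel for one sample of a small matrix:
# literal ecdf, rank folding and deviation walk.
oracle_gsva_none_es <- function(m, j, set_genes, tau, max_diff) {
  n <- nrow(m)
  z <- numeric(n)
  for (i in seq_len(n)) z[i] <- mean(m[i, ] <= m[i, j])
  rk <- rank(z, ties.method = "average")
  dec_rk <- n + 1 - rk
  stat <- abs(n / 2 - dec_rk)
  ord <- order(-z, rownames(m))
  inset <- rownames(m)[ord] %in% set_genes
  st <- stat[ord]
  denom_in <- sum(st[inset]^tau)
  p_in <- 0; p_out <- 0
  v <- numeric(n)
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + st[i]^tau / denom_in
    else p_out <- p_out + 1 / (n - sum(inset))
    v[i] <- p_in - p_out
  }
  if (max_diff) max(c(0, v)) + min(c(0, v)) else v[which.max(abs(v))]
}

# classic GSEA walk (weight exponent 1, signed maximum deviation) over a
# supplied per-gene statistic
oracle_gsea_es <- function(stat, set_genes) {
  ord <- order(-stat, names(stat))
  ids <- names(stat)[ord]
  w <- abs(stat)[ord]
  inset <- ids %in% set_genes
  denom_in <- sum(w[inset])
  p_in <- 0; p_out <- 0; best <- 0
  for (i in seq_along(ids)) {
    if (inset[i]) p_in <- p_in + w[i] / denom_in
    else p_out <- p_out + 1 / (length(ids) - sum(inset))
    if (abs(p_in - p_out) > abs(best)) best <- p_in - p_out
  }
  best
}

# hand product-limit estimator by explicit loop over distinct event times
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (k in seq_along(et)) {
    t <- et[k]
    n_i <- sum(time >= t)
    d_i <- sum(time == t & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[k] <- s
  }
  list(times = et, survival = surv)
}

# hand observed-minus-expected log-rank tabulation, one event time at a time
oracle_logrank_chisq <- function(time, event, g1) {
  et <- sort(unique(time[event == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in et) {
    at <- time >= t
    n_i <- sum(at)
    n1_i <- sum(at & g1)
    d_i <- sum(time == t & event == 1)
    d1_i <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1_i
    e1 <- e1 + d_i * n1_i / n_i
    if (n_i > 1)
      v <- v + d_i * (n1_i / n_i) * (1 - n1_i / n_i) * (n_i - d_i) / (n_i - 1)
  }
  if (v == 0) 0 else (o1 - e1)^2 / v
}

# small deterministic expression matrix fixture
make_expr <- function(values, genes = NULL, samples = NULL,
                      scale_tag = "log2") {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale_tag)
}
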