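# Inverse of the trigamma function by bisection on log(y), tolerance 1e-8.
# trigamma is strictly decreasing on (0, Inf) with range (0, Inf).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(NA_real_)
  lo <- -30; hi <- 30   # log scale: y in (1e-13, 1e13)
  if (trigamma(exp(lo)) < x || trigamma(exp(hi)) > x) return(NA_real_)
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (trigamma(exp(mid)) > x) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

# Moment-matched fit of the inverse-chi-square variance prior (d0, s0^2)
# from per-feature sample variances s2 on d residual df: the log sample
# variances follow a shifted log-F, so their mean and spread identify the
# prior via digamma / trigamma moments.
fit_variance_prior <- function(s2, d) {
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (length(s2) < 2L) return(list(d0 = 0, s0_2 = NA_real_, ok = FALSE))
  e <- log(s2)
  evar <- stats::var(e)
  target <- evar - trigamma(d / 2)
  if (!is.finite(target)) return(list(d0 = 0, s0_2 = NA_real_, ok = FALSE))
  if (target <= 0) {
    # no excess spread beyond chi-square sampling noise: infinite prior df,
    # common variance estimated by the plain mean of the sample variances
    return(list(d0 = Inf, s0_2 = mean(s2), ok = TRUE))
  }
  half_d0 <- trigamma_inverse(target)
  if (is.na(half_d0)) return(list(d0 = 0, s0_2 = NA_real_, ok = FALSE))
  d0 <- 2 * half_d0
  s0_2 <- exp(mean(e) - digamma(d / 2) + log(d / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2, ok = TRUE)
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per feature (gene or pathway score): the effect is the plain difference
#' of class means (class 1 minus class 0; effects are never shrunk), while
#' the residual variance is shrunk toward a common prior: the posterior
#' variance is `(d0 * s0^2 + d * s^2) / (d0 + d)` with the prior
#' `(d0, s0^2)` fitted by moment-matching the distribution of log sample
#' variances to a scaled F. The moderated t is the effect over the
#' posterior standard error, on `d0 + d` degrees of freedom. `d0 = 0`
#' reproduces the classical equal-variance t exactly; `d0 = Inf` uses the
#' common prior variance for every feature.
#'
#' @param m numeric matrix ([expression_matrix()], [score_matrix()] or
#'   plain matrix), features x samples.
#' @param labels two-class vector, one per sample; the second factor level
#'   is class 1.
#' @param d0 optional prior degrees of freedom override; `NULL` fits by
#'   moment matching (falling back to `d0 = 0`, i.e. the ordinary t, with a
#'   warning if the fit is degenerate).
#' @return data.frame of class `"differential_result"`: `feature`,
#'   `effect`, `t_mod`, `pvalue`, `padj`, `selected` (all `NA` until
#'   [select_features()] is applied); attributes `d0`, `s0_2`, `df_total`.
#' @export
moderated_t_test <- function(m, labels, d0 = NULL) {
  m <- unclass(m)
  if (!is.matrix(m) || !is.numeric(m))
    stop("`m` must be a numeric features x samples matrix", call. = FALSE)
  if (length(labels) != ncol(m))
    stop("`labels` must have one entry per sample", call. = FALSE)
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("`labels` must have exactly two classes", call. = FALSE)
  if (any(table(f) < 2L))
    stop("each class needs >= 2 samples", call. = FALSE)
  is1 <- f == levels(f)[2L]
  n1 <- sum(is1); n0 <- sum(!is1)
  x1 <- m[, is1, drop = FALSE]; x0 <- m[, !is1, drop = FALSE]
  mu1 <- rowMeans(x1); mu0 <- rowMeans(x0)
  ss1 <- rowSums((x1 - mu1)^2); ss0 <- rowSums((x0 - mu0)^2)
  d <- n1 + n0 - 2L
  s2 <- (ss1 + ss0) / d
  if (any(s2 == 0))
    warning(sum(s2 == 0), " feature(s) with zero residual variance",
            call. = FALSE)
  if (is.null(d0)) {
    fit <- fit_variance_prior(s2, d)
    if (!fit$ok) {
      warning("variance-prior fit did not converge; falling back to the ",
              "ordinary t (d0 = 0)", call. = FALSE)
      fit <- list(d0 = 0, s0_2 = 0)
    }
    d0 <- fit$d0; s0_2 <- fit$s0_2
  } else {
    s0_2 <- if (d0 > 0) fit_variance_prior(s2, d)$s0_2 else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  effect <- mu1 - mu0
  t_mod <- effect / se
  df_total <- d0 + d
  pvalue <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(feature = rownames(m), effect = effect, t_mod = t_mod,
                    pvalue = pvalue, padj = bh_adjust(pvalue),
                    selected = NA, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_2") <- s0_2
  attr(res, "df_total") <- df_total
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Apply the effect-size / FDR selection rule
#'
#' Marks features with `|effect| >= effect_threshold` and
#' `padj < alpha` as selected (both up- and down-regulated features
#' qualify) and reports the count.
#'
#' @param results a `"differential_result"` from [moderated_t_test()].
#' @param effect_threshold minimum absolute effect (log2 fold change for
#'   gene matrices; score difference for pathway matrices).
#' @param alpha B-H adjusted p-value cutoff.
#' @return `results` with the `selected` column filled.
#' @export
select_features <- function(results, effect_threshold = 1.5, alpha = 0.05) {
  stopifnot(inherits(results, "differential_result") || is.data.frame(results))
  if (nrow(results) == 0L) stop("`results` is empty", call. = FALSE)
  results$selected <- abs(results$effect) >= effect_threshold &
    results$padj < alpha
  message(sum(results$selected), " of ", nrow(results),
          " feature(s) selected at |effect| >= ", effect_threshold,
          ", padj < ", alpha)
  results
}

#' Sorted intersection of two gene lists
#'
#' @param a,b character vectors of gene symbols.
#' @return sorted character vector of the shared symbols.
#' @export
intersect_gene_lists <- function(a, b) {
  sort(intersect(trimws(as.character(a)), trimws(as.character(b))))
}
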