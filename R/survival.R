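#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survivor function S(t) = prod_{t_i <= t}
#' (1 - d_i / n_i) over the distinct event times of one annotation group.
#'
#' @param ann a [cohort_annotations()].
#' @param group optional group label; `NULL` uses all rows.
#' @return list of class `"km_curve"`: `times` (distinct event times),
#'   `survival` (step values), `at_risk`, `events`, `n`.
#' @export
km_estimate <- function(ann, group = NULL) {
  stopifnot(inherits(ann, "cohort_annotations"))
  if (!is.null(group)) ann <- ann[ann$group == group, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no samples in the requested group", call. = FALSE)
  time <- ann$time
  event <- ann$event
  et <- sort(unique(time[event == 1L]))
  if (length(et) == 0L) {
    res <- list(times = numeric(0), survival = numeric(0),
                at_risk = integer(0), events = integer(0), n = nrow(ann))
    class(res) <- "km_curve"
    return(res)
  }
  at_risk <- vapply(et, function(t) sum(time >= t), 0L)
  events <- vapply(et, function(t) sum(time == t & event == 1L), 0L)
  surv <- cumprod(1 - events / at_risk)
  res <- list(times = et, survival = surv, at_risk = at_risk,
              events = events, n = nrow(ann))
  class(res) <- "km_curve"
  res
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event times, S(max) = %s\n", x$n,
              length(x$times),
              if (length(x$survival)) signif(min(x$survival), 4) else 1))
  invisible(x)
}

# Two-group log-rank chi-square on raw vectors; g1 logical (group-1 flag).
# Single O(n log n) pass over the distinct times, so the cutpoint scan can
# call it once per candidate split.
logrank_stat <- function(time, event, g1) {
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; g_s <- g1[o]
  n <- length(t_s)
  first <- !duplicated(t_s)
  starts <- which(first)                       # first row of each distinct time
  tid <- cumsum(first)                         # distinct-time index per row
  n_at <- n - starts + 1                       # at risk at each distinct time
  n1_tail <- rev(cumsum(rev(g_s)))             # group-1 at risk
  n1_at <- n1_tail[starts]
  nt <- length(starts)
  d <- tabulate(tid[e_s == 1L], nbins = nt)    # events per distinct time
  d1 <- tabulate(tid[e_s == 1L & g_s], nbins = nt)
  keep <- d > 0L
  d <- d[keep]; d1 <- d1[keep]
  n_at <- n_at[keep]; n1_at <- n1_at[keep]
  o1 <- sum(d1)
  e1 <- sum(d * n1_at / n_at)
  ok <- n_at > 1L
  v <- sum((d * (n1_at / n_at) * (1 - n1_at / n_at) *
              (n_at - d) / (n_at - 1))[ok])
  if (v == 0) return(c(statistic = 0, o1 = o1, e1 = e1))
  c(statistic = (o1 - e1)^2 / v, o1 = o1, e1 = e1)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with 1 degree of
#' freedom; symmetric in the group labels.
#'
#' @param ann a [cohort_annotations()] whose `group` column has the two
#'   compared labels.
#' @param groups optional character vector of the two labels to compare;
#'   defaults to the two labels present.
#' @return list of class `"logrank_result"`: `statistic`, `df`, `pvalue`.
#' @export
logrank_test <- function(ann, groups = NULL) {
  stopifnot(inherits(ann, "cohort_annotations"))
  if (is.null(groups)) groups <- sort(unique(ann$group))
  if (length(groups) != 2L)
    stop("log-rank test needs exactly two group labels", call. = FALSE)
  ann <- ann[ann$group %in% groups, , drop = FALSE]
  if (!all(groups %in% ann$group))
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(ann$event) == 0L)
    stop("log-rank test needs at least one event", call. = FALSE)
  s <- logrank_stat(ann$time, ann$event, ann$group == groups[2L])
  res <- list(statistic = unname(s["statistic"]), df = 1L,
              pvalue = stats::pchisq(unname(s["statistic"]), df = 1,
                                     lower.tail = FALSE))
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chisq = %s on %d df, p = %s\n",
              signif(x$statistic, 4), x$df, signif(x$pvalue, 4)))
  invisible(x)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every observed score value whose "low = score < value" split keeps
#' both groups at least `minprop` of the cohort, and returns the cutoff
#' maximizing the two-group log-rank statistic (ties broken toward the
#' smaller cutoff). No multiplicity correction is applied to the reported
#' p-value; `candidates_evaluated` is returned so users can correct it.
#'
#' @param values per-sample scores, in the order of `ann` rows (or named by
#'   sample id, in which case they are matched to `ann$sample_id`).
#' @param ann a [cohort_annotations()] with `time` and `event`.
#' @param minprop minimum proportion of samples in each resulting group.
#' @return list of class `"cutpoint_result"`: `cutoff`, `statistic`,
#'   `pvalue`, `candidates_evaluated`, `minprop`.
#' @export
optimal_cutpoint <- function(values, ann, minprop = 0.10) {
  stopifnot(inherits(ann, "cohort_annotations"))
  if (!is.null(names(values))) {
    idx <- match(ann$sample_id, names(values))
    if (anyNA(idx)) stop("named `values` must cover every sample", call. = FALSE)
    values <- unname(values[idx])
  }
  if (length(values) != nrow(ann))
    stop("`values` must have one score per annotation row", call. = FALSE)
  if (sum(ann$event) < 10L)
    stop("cutpoint search needs >= 10 samples with events", call. = FALSE)
  n <- length(values)
  cand <- sort(unique(values))
  lo_n <- vapply(cand, function(v) sum(values < v), 0L)
  ok <- lo_n >= ceiling(minprop * n) & (n - lo_n) >= ceiling(minprop * n)
  cand <- cand[ok]
  if (length(cand) == 0L)
    stop("no admissible split keeps both groups >= minprop of samples",
         call. = FALSE)
  stats_at <- vapply(cand, function(v)
    logrank_stat(ann$time, ann$event, values < v)[["statistic"]], 0)
  best <- which.max(stats_at)   # which.max takes the first = smallest cutoff
  res <- list(cutoff = cand[best], statistic = stats_at[best],
              pvalue = stats::pchisq(stats_at[best], df = 1,
                                     lower.tail = FALSE),
              candidates_evaluated = length(cand), minprop = minprop)
  class(res) <- "cutpoint_result"
  res
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "<cutpoint> cutoff = %s, log-rank chisq = %s (p = %s), %d candidates\n",
    signif(x$cutoff, 4), signif(x$statistic, 4), signif(x$pvalue, 4),
    x$candidates_evaluated))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic sum (O - E)^2 / E without continuity correction, the
#' convention that reproduces the printed clinicopathologic p-values from
#' 2x2 counts. The small-expected-count approximation warning from the
#' underlying test is suppressed; the expected-count matrix is returned so
#' callers can judge adequacy themselves.
#'
#' @param table contingency matrix of non-negative counts, at least 2x2,
#'   with no all-zero row or column.
#' @return list of class `"chisq_result"`: `statistic`, `df`, `pvalue`,
#'   `expected`.
#' @export
chisq_independence <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("`table` must be a numeric matrix of counts", call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (any(table < 0) || sum(table) <= 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has an all-zero row or column", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  res <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
              pvalue = ct$p.value, expected = ct$expected)
  class(res) <- "chisq_result"
  res
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq> X2 = %s on %d df, p = %s\n", signif(x$statistic, 6),
              x$df, signif(x$pvalue, 4)))
  invisible(x)
}
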