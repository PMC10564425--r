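ann_from <- function(time, event, group = "g") {
  cohort_annotations(data.frame(
    sample_id = paste0("s", seq_along(time)), group = group,
    time = time, event = as.integer(event)))
}

test_that("KM estimate matches hand product-limit values", {
  km <- km_estimate(ann_from(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$times, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  flat <- km_estimate(ann_from(c(5, 6, 7), c(0, 0, 0)))
  expect_length(flat$times, 0)  # no events: curve stays at 1

  # a censored subject adds no step, but enlarges every risk set it is in
  km2 <- km_estimate(ann_from(c(1, 2, 3, 10), c(1, 1, 1, 0)))
  expect_equal(km2$times, km$times)
  expect_equal(km2$at_risk, c(4L, 3L, 2L))
  expect_equal(km2$survival, c(3 / 4, 1 / 2, 1 / 4))
})

test_that("KM agrees with the survival package and the loop oracle", {
  skip_if_not_installed("survival")
  set.seed(17)
  time <- round(rexp(40, 0.1), 2) + 0.01
  event <- rbinom(40, 1, 0.7)
  km <- km_estimate(ann_from(time, event))
  or <- oracle_km(time, event)
  expect_equal(km$times, or$times)
  expect_equal(km$survival, or$survival, tolerance = 1e-12)

  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  ref <- summary(sf, times = km$times)
  expect_equal(km$survival, ref$surv, tolerance = 1e-10)
})

test_that("KM curve of a duplicated merged cohort equals the single-cohort curve", {
  set.seed(23)
  time <- round(rexp(25, 0.05), 1) + 0.1
  event <- rbinom(25, 1, 0.6)
  one <- km_estimate(ann_from(time, event))
  two <- km_estimate(ann_from(rep(time, 2), rep(event, 2)))
  expect_equal(two$times, one$times)
  expect_equal(two$survival, one$survival, tolerance = 1e-12)
})

test_that("log-rank matches the hand tabulation and survdiff", {
  # 6-subject toy table, tabulated by the loop oracle
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  grp <- c("A", "B", "A", "B", "A", "B")
  ann <- ann_from(time, event, grp)
  res <- logrank_test(ann)
  expect_equal(res$statistic,
               oracle_logrank_chisq(time, event, grp == "B"),
               tolerance = 1e-10)

  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(res$statistic, sd$chisq, tolerance = 1e-10)

  set.seed(29)
  time2 <- rexp(60, 0.1); event2 <- rbinom(60, 1, 0.8)
  grp2 <- sample(c("A", "B"), 60, replace = TRUE)
  res2 <- logrank_test(ann_from(time2, event2, grp2))
  sd2 <- survival::survdiff(survival::Surv(time2, event2) ~ grp2)
  expect_equal(res2$statistic, sd2$chisq, tolerance = 1e-10)
})

test_that("log-rank is symmetric in labels and null on duplicated groups", {
  set.seed(31)
  time <- rexp(30, 0.1); event <- rbinom(30, 1, 0.8)
  dup <- ann_from(rep(time, 2), rep(event, 2),
                  rep(c("A", "B"), each = 30))
  res <- logrank_test(dup)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$pvalue, 1)

  grp <- sample(c("A", "B"), 30, replace = TRUE)
  a <- logrank_test(ann_from(time, event, grp), c("A", "B"))
  b <- logrank_test(ann_from(time, event, grp), c("B", "A"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  expect_error(logrank_test(ann_from(c(1, 2), c(0, 0), c("A", "B"))),
               "event")
})

test_that("optimal cutpoint equals a brute-force scan over admissible splits", {
  set.seed(37)
  n <- 50
  score <- runif(n)
  time <- rexp(n, ifelse(score < 0.4, 0.15, 0.04))
  event <- as.integer(time <= runif(n, 0, 30))
  time <- pmin(time, runif(n, 0, 30)) + 1e-9
  ann <- ann_from(time, event)

  res <- optimal_cutpoint(score, ann, minprop = 0.1)

  cand <- sort(unique(score))
  lo_n <- vapply(cand, function(v) sum(score < v), 0L)
  ok <- lo_n >= ceiling(0.1 * n) & (n - lo_n) >= ceiling(0.1 * n)
  stats_bf <- vapply(cand[ok], function(v)
    oracle_logrank_chisq(time, event, score < v), 0)
  expect_equal(res$statistic, max(stats_bf), tolerance = 1e-10)
  expect_equal(res$cutoff, cand[ok][which.max(stats_bf)])
  expect_identical(res$candidates_evaluated, sum(ok))
})

test_that("cutpoint split is rank-invariant and rejects degenerate scores", {
  set.seed(41)
  n <- 60
  score <- runif(n)
  time <- rexp(n, 0.1); event <- rep(1L, n)
  ann <- ann_from(time, event)
  res <- optimal_cutpoint(score, ann)
  res_t <- optimal_cutpoint(qnorm(score * 0.98 + 0.01), ann)
  expect_identical(score < res$cutoff,
                   qnorm(score * 0.98 + 0.01) < res_t$cutoff)
  expect_equal(res$statistic, res_t$statistic, tolerance = 1e-12)

  expect_error(optimal_cutpoint(rep(1, n), ann), "no admissible split")
  expect_error(optimal_cutpoint(score[1:9], ann_from(time[1:9], event[1:9])),
               ">= 10")
})

test_that("Pearson chi-square reproduces the clinicopathologic p-values", {
  t1 <- wdfy4_table1()
  expect_equal(chisq_independence(t1$tumor_location)$pvalue, 0.0267,
               tolerance = 1e-2)
  expect_equal(round(chisq_independence(t1$tumor_location)$pvalue, 4), 0.0267)
  expect_equal(round(chisq_independence(t1$tumor_size)$pvalue, 4), 0.7931)
  expect_equal(round(chisq_independence(t1$lymph_node)$pvalue, 4), 0.8378)
  expect_equal(round(chisq_independence(t1$tnm_stage)$pvalue, 3), 0.217)
  expect_equal(round(chisq_independence(t1$path_grade)$pvalue, 4), 0.6007)
})

test_that("chi-square contracts: exact independence, transpose, margins", {
  flat <- chisq_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$pvalue, 1)

  m <- matrix(c(9, 47, 1, 41), 2, byrow = TRUE)
  expect_equal(chisq_independence(m)$statistic,
               chisq_independence(t(m))$statistic, tolerance = 1e-12)
  expect_equal(sum(chisq_independence(m)$expected), sum(m))

  expect_error(chisq_independence(matrix(c(0, 0, 5, 3), 2, byrow = TRUE)),
               "all-zero")
  expect_error(chisq_independence(matrix(1:3, 1)), "2x2")
})
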