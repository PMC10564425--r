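two_class_matrix <- function(n_feat = 50, n1 = 5, n0 = 5, shift = 0,
                             seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * (n1 + n0)), n_feat,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(n1 + n0))))
  m[, seq_len(n1) + n0] <- m[, seq_len(n1) + n0] + shift
  list(m = m, labels = rep(c("c0", "c1"), c(n0, n1)))
}

test_that("d0 = 0 reproduces the classical equal-variance t exactly", {
  d <- two_class_matrix(seed = 3)
  res <- suppressWarnings(moderated_t_test(d$m, d$labels, d0 = 0))
  for (i in c(1, 17, 50)) {
    tt <- t.test(d$m[i, d$labels == "c1"], d$m[i, d$labels == "c0"],
                 var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$pvalue[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$effect[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
})

test_that("effects are unshrunk class-mean differences; label swap negates them", {
  d <- two_class_matrix(shift = 1, seed = 5)
  res <- moderated_t_test(d$m, d$labels)
  expect_equal(res$effect,
               rowMeans(d$m[, d$labels == "c1"]) -
                 rowMeans(d$m[, d$labels == "c0"]),
               ignore_attr = TRUE, tolerance = 1e-12)

  flipped <- moderated_t_test(d$m, factor(d$labels, levels = c("c1", "c0")))
  expect_equal(flipped$effect, -res$effect, tolerance = 1e-12)
  expect_equal(flipped$t_mod, -res$t_mod, tolerance = 1e-12)
  expect_equal(flipped$pvalue, res$pvalue, tolerance = 1e-12)
})

test_that("equal sample variances push d0 to infinity and keep the |t| order", {
  d <- two_class_matrix(n_feat = 30, seed = 7)
  m <- d$m
  # rescale each feature's residuals so every sample variance is exactly 1
  is1 <- d$labels == "c1"
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    r[is1] <- r[is1] - mean(r[is1]); r[!is1] <- r[!is1] - mean(r[!is1])
    s <- sqrt(sum(r^2) / (length(r) - 2))
    m[i, ] <- r / s + rep(c(0, i / 10), c(sum(!is1), sum(is1)))
  }
  res <- moderated_t_test(m, d$labels)
  expect_identical(attr(res, "d0"), Inf)
  expect_equal(attr(res, "s0_2"), 1, tolerance = 1e-6)
  t_ord <- moderated_t_test(m, d$labels, d0 = 0)
  expect_identical(order(abs(res$t_mod)), order(abs(t_ord$t_mod)))
})

test_that("moderated t matches limma's empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  # heteroscedastic features (inverse-chi-square variances) so the fitted
  # prior degrees of freedom are finite and shrinkage is active
  set.seed(10)
  sds <- sqrt(8 / rchisq(400, df = 8))
  m <- matrix(rnorm(400 * 12, sd = rep(sds, 12)), 400,
              dimnames = list(paste0("f", 1:400), paste0("s", 1:12)))
  labels <- rep(c("c0", "c1"), each = 6)
  m[1:40, labels == "c1"] <- m[1:40, labels == "c1"] + 1
  res <- moderated_t_test(m, labels)
  design <- cbind(1, labels == "c1")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_true(is.finite(attr(res, "d0")))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_2"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, fit$t[, 2], ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(res$pvalue, fit$p.value[, 2], ignore_attr = TRUE,
               tolerance = 1e-6)

  # homoscedastic data drive the prior df to infinity in both codebases
  d <- two_class_matrix(n_feat = 300, n1 = 6, n0 = 6, shift = 0.8, seed = 9)
  res2 <- moderated_t_test(d$m, d$labels)
  fit2 <- limma::eBayes(limma::lmFit(d$m, cbind(1, d$labels == "c1")))
  expect_identical(attr(res2, "d0"), fit2$df.prior)
  expect_equal(attr(res2, "s0_2"), fit2$s2.prior, tolerance = 1e-9)
  expect_equal(res2$t_mod, fit2$t[, 2], ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("null data give approximately uniform p-values and no discoveries", {
  d <- two_class_matrix(n_feat = 2000, n1 = 6, n0 = 6, seed = 11)
  res <- moderated_t_test(d$m, d$labels)
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_identical(sum(res$padj < 0.05), 0L)
})

test_that("selection applies the absolute-effect and FDR rule", {
  res <- data.frame(feature = c("up", "down", "weak", "ns"),
                    effect = c(2, -2, 0.5, 3),
                    t_mod = c(5, -5, 1, 1.5),
                    pvalue = c(1e-4, 1e-4, 0.3, 0.2),
                    padj = c(0.01, 0.01, 0.4, 0.3), selected = NA)
  class(res) <- c("differential_result", "data.frame")
  sel <- suppressMessages(select_features(res, 1.5, 0.05))
  expect_identical(sel$feature[sel$selected], c("up", "down"))
  none <- suppressMessages(select_features(res, Inf, 0.05))
  expect_false(any(none$selected))
})

test_that("gene-list intersection is sorted and set-like", {
  expect_identical(
    intersect_gene_lists(c("WDFY4", "MS4A1", "TLR10"),
                         c("WDFY4", "TP53INP1")),
    "WDFY4")
  expect_identical(intersect_gene_lists(c("A", "B"), c("C")), character(0))
  a <- c("ZZZ", "AAA", "MMM")
  expect_identical(intersect_gene_lists(a, a), sort(a))
})
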