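test_that("ssGSEA matches a literal summation oracle on tiny fixtures", {
  # canonical 5-gene case: values 5..1, set {g1, g2}, alpha 0.25
  m <- make_expr(matrix(c(5, 4, 3, 2, 1), 5, 1))
  sets <- gene_set_collection(list(S = c("g1", "g2")))
  got <- ssgsea_scores(m, sets, alpha = 0.25, normalize = FALSE)
  want <- oracle_ssgsea_es(setNames(m[, 1], rownames(m)), c("g1", "g2"), 0.25)
  expect_equal(unname(got["S", 1]), want, tolerance = 1e-12)

  # randomized multi-sample, multi-set fixtures against the same oracle
  set.seed(42)
  for (rep in 1:5) {
    mm <- make_expr(matrix(rnorm(8 * 3), 8, 3))
    ss <- gene_set_collection(list(A = sample(rownames(mm), 3),
                                   B = sample(rownames(mm), 5)))
    got <- ssgsea_scores(mm, ss, alpha = 0.25, normalize = FALSE)
    for (k in c("A", "B")) for (j in 1:3) {
      expect_equal(unname(got[k, j]),
                   oracle_ssgsea_es(setNames(mm[, j], rownames(mm)),
                                    ss[[k]], 0.25),
                   tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA normalization divides by the global score range", {
  set.seed(5)
  mm <- make_expr(matrix(rnorm(20 * 4), 20, 4))
  ss <- gene_set_collection(list(A = rownames(mm)[1:4], B = rownames(mm)[5:12]))
  raw <- ssgsea_scores(mm, ss, normalize = FALSE)
  nrm <- ssgsea_scores(mm, ss, normalize = TRUE)
  expect_equal(unclass(nrm), unclass(raw) / (max(raw) - min(raw)),
               tolerance = 1e-12)
})

test_that("ssGSEA is rank-based: monotone transforms and rank ties", {
  set.seed(7)
  x <- rnorm(10)
  m <- make_expr(cbind(x, exp(x) + 3))      # second sample = monotone map
  sets <- gene_set_collection(list(S = rownames(m)[c(1, 4, 7)]))
  sc <- ssgsea_scores(m, sets, normalize = FALSE)
  expect_equal(sc[1, 1], sc[1, 2], tolerance = 1e-12)
})

test_that("ssGSEA rejects degenerate sets", {
  m <- make_expr(matrix(1:6 * 1.0, 3, 2))
  expect_error(
    ssgsea_scores(m, gene_set_collection(list(ALL = rownames(m)))),
    "covering every gene")
  expect_error(
    ssgsea_scores(m, gene_set_collection(list(NONE = "zz"))),
    "NONE")
})

test_that("GSVA empirical-CDF scores equal the brute-force walk oracle", {
  set.seed(9)
  m <- make_expr(matrix(rnorm(6 * 4), 6, 4))
  sets <- gene_set_collection(list(A = rownames(m)[1:2],
                                   B = rownames(m)[c(3, 5, 6)]))
  for (md in c(TRUE, FALSE)) {
    got <- gsva_scores(m, sets, tau = 1, max_diff = md, kcdf = "none")
    for (k in c("A", "B")) for (j in 1:4) {
      expect_equal(unname(got[k, j]),
                   oracle_gsva_none_es(unclass(m), j, sets[[k]], 1, md),
                   tolerance = 1e-12)
    }
  }
})

test_that("GSVA responds to relative enrichment and sample permutation", {
  # GSVA scores are relative across samples: a set up-shifted in one
  # sample (against that gene's cross-sample distribution) scores highest
  # and positive in that sample
  set.seed(13)
  base <- matrix(rnorm(10 * 6), 10, 6)
  base[1:3, 1] <- base[1:3, 1] + 5
  m <- make_expr(base)
  sets <- gene_set_collection(list(TOP = rownames(m)[1:3]))
  sc <- gsva_scores(m, sets, kcdf = "gaussian")
  expect_gt(sc["TOP", 1], 0)
  expect_identical(which.max(sc["TOP", ]), c(s1 = 1L))

  perm <- c(3, 1, 6, 2, 5, 4)
  m2 <- expression_matrix(unclass(m)[, perm], "log2")
  sc2 <- gsva_scores(m2, sets, kcdf = "gaussian")
  expect_equal(unclass(sc2), unclass(sc)[, perm, drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(gsva_scores(make_expr(matrix(rnorm(30), 10, 3)), sets),
               ">= 4 samples")
})

test_that("GSEA permutation p is consistent with exhaustive enumeration", {
  set.seed(21)
  n <- 8
  m <- make_expr(matrix(rnorm(12 * n), 12, n))
  m[1:5, 5:8] <- m[1:5, 5:8] + 1.2
  labels <- rep(c("c0", "c1"), each = 4)
  sets <- gene_set_collection(list(UP = rownames(m)[1:5],
                                   NULLSET = rownames(m)[6:11]))

  # exhaustive null: every way to choose which 4 samples carry class 1
  combos <- utils::combn(n, 4)
  null_es <- matrix(NA_real_, ncol(combos), 2)
  for (b in seq_len(ncol(combos))) {
    l1 <- seq_len(n) %in% combos[, b]
    x1 <- unclass(m)[, l1]; x0 <- unclass(m)[, !l1]
    s2n <- (rowMeans(x1) - rowMeans(x0)) /
      (apply(x1, 1, sd) + apply(x0, 1, sd))
    names(s2n) <- rownames(m)
    null_es[b, ] <- c(oracle_gsea_es(s2n, sets$UP),
                      oracle_gsea_es(s2n, sets$NULLSET))
  }
  obs_l1 <- labels == "c1"
  x1 <- unclass(m)[, obs_l1]; x0 <- unclass(m)[, !obs_l1]
  s2n <- (rowMeans(x1) - rowMeans(x0)) / (apply(x1, 1, sd) + apply(x0, 1, sd))
  names(s2n) <- rownames(m)
  es_obs <- unname(c(oracle_gsea_es(s2n, sets$UP),
                     oracle_gsea_es(s2n, sets$NULLSET)))
  # exceedance counted with a small tolerance: the null has atoms exactly
  # at |es_obs| (the observed labelling is one of the combinations) and
  # the two code paths differ at the last floating-point digit
  p_exact <- colMeans(abs(null_es) >=
                        matrix(abs(es_obs) - 1e-9, ncol(combos), 2,
                               byrow = TRUE))

  n_perm <- 2000
  res <- gsea_two_group(m, labels, sets, min_size = 3, max_size = 20,
                        n_perm = n_perm, seed = 99)
  expect_equal(res$es, es_obs, tolerance = 1e-12)
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_true(all(abs(res$pvalue - p_exact) <=
                    3 * mc_se + 2 / (n_perm + 1)))
})

test_that("GSEA excludes sets outside the size window and reports them", {
  set.seed(31)
  m <- make_expr(matrix(rnorm(30 * 10), 30, 10))
  labels <- rep(0:1, each = 5)
  sets <- gene_set_collection(list(SMALL = rownames(m)[1:9],
                                   OK = rownames(m)[1:12]))
  res <- gsea_two_group(m, labels, sets, min_size = 10, max_size = 500,
                        n_perm = 50, seed = 1)
  expect_identical(res$set_name, "OK")
  expect_identical(attr(res, "excluded"), "SMALL")
  expect_error(gsea_two_group(m, labels, sets["SMALL"], min_size = 10,
                              max_size = 500, n_perm = 10, seed = 1),
               "no gene set")
})

test_that("a planted up-shifted set reaches significance with permutations", {
  set.seed(55)
  n <- 40
  m <- matrix(rnorm(400 * n), 400, n,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:n)))
  labels <- rep(c("a", "b"), each = n / 2)
  m[1:20, labels == "b"] <- m[1:20, labels == "b"] + 1
  expr <- expression_matrix(m, "log2")
  sets <- gene_set_collection(list(PLANTED = paste0("g", 1:20),
                                   RANDOM = paste0("g", 101:130)))
  res <- gsea_two_group(expr, labels, sets, n_perm = 1000, seed = 7)
  planted <- res[res$set_name == "PLANTED", ]
  expect_gt(planted$es, 0)
  expect_lt(planted$padj, 0.05)
})

test_that("B-H adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.03, 0.01, 0.02)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone step-up
})
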