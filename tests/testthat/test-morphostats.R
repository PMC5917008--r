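# ROC screening, feature selection, PCA compound score, group tests, and
# manual-vs-automated agreement.

test_that("AUC: perfect separation, chance, and the tied-pair construction", {
  r <- roc_auc(c(1, 2, 3, 4, 5, 6), rep(c("b", "a"), each = 3),
               positive = "a")
  expect_equal(r$auc_raw, 1)
  expect_equal(r$auc, 1)
  expect_identical(r$direction, "a")
  same <- roc_auc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                  positive = "a")
  expect_equal(same$auc_raw, 0.5)
  # {1,3,2} (cases) vs {2,4,5}: pairwise wins 1.5 of 9 -> raw 7.5/9 folded
  mix <- roc_auc(c(1, 3, 2, 2, 4, 5), rep(c("pos", "neg"), each = 3),
                 positive = "pos")
  expect_equal(mix$auc_raw, 1.5 / 9)
  expect_equal(mix$auc, 7.5 / 9)
  expect_identical(mix$direction, "neg")
  expect_error(roc_auc(1:3, c("a", "a", "a")), "two levels")
})

test_that("pairwise AUC equals trapezoidal ROC integration on random data", {
  for (s in 1:100) {
    microglia3d:::with_seed(1000 + s, {
      n1 <- sample(3:12, 1)
      n2 <- sample(3:12, 1)
      pos <- round(rnorm(n1, 0.5), 1)  # rounding forces ties
      neg <- round(rnorm(n2, 0), 1)
      r <- roc_auc(c(pos, neg), rep(c("p", "n"), c(n1, n2)), positive = "p")
      expect_equal(r$auc_raw, trapezoid_auc(pos, neg), tolerance = 1e-12)
    })
  }
})

fake_roc <- function(features, aucs, tags = NULL) {
  roster <- feature_roster()
  idx <- match(features, roster$feature)
  tibble::tibble(
    feature = features,
    family = roster$family[idx],
    percentile_tag = if (is.null(tags)) roster$percentile_tag[idx] else tags,
    auc_raw = aucs, auc = pmax(aucs, 1 - aucs),
    direction = "a", n_positive = 10, n_negative = 10)
}

test_that("feature selection keeps one best variant per percentile family", {
  roc <- fake_roc(c("Volume min", "Volume P75", "Sphericity"),
                  c(0.80, 0.93, 0.90))
  sel <- select_features(roc, auc_cutoff = 0.85)
  expect_setequal(sel, c("Sphericity", "Volume P75"))
  expect_false("Volume min" %in% sel)
  # AUC tie inside a family goes to the lower percentile tag
  tie <- fake_roc(c("Closeness P25", "Closeness P75"), c(0.9, 0.9))
  expect_identical(select_features(tie), "Closeness P25")
  # nothing above the cutoff: empty selection with a warning
  low <- fake_roc(c("Sphericity", "Nodes total"), c(0.6, 0.7))
  expect_warning(none <- select_features(low), "cutoff")
  expect_length(none, 0)
  # a full screen never keeps two variants of one family
  cs <- cached_stack_result()
  ft <- cs$result$features
  labels <- rep(c("g1", "g2"), length.out = nrow(ft))
  scr <- roc_screen(ft, labels = labels)
  sel2 <- select_features(scr, auc_cutoff = 0)
  bases <- sub(" (min|P25|P50|P75|max)$", "", sel2)
  expect_false(anyDuplicated(bases) > 0)
})

test_that("correlation matrix is symmetric with unit diagonal and flags degeneracy", {
  t0 <- tibble::tibble(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2,
                       c = -c(1, 2, 3, 4), d = c(2, 1, 4, 3))
  m <- correlation_matrix(t0, c("a", "b", "c", "d"))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  t1 <- tibble::tibble(a = c(1, 2, 3), z = c(5, 5, 5))
  expect_warning(mz <- correlation_matrix(t1, c("a", "z")), "zero-variance")
  expect_equal(mz["a", "z"], 0)
  expect_equal(mz["z", "z"], 1)
})

test_that("PCA compound score: rank-1, isotropic, and 1-factor recovery", {
  x <- c(1, 4, 2, 8, 5, 7)
  t_rank1 <- tibble::tibble(f1 = x, f2 = 3 * x + 2)
  p1 <- pca_compound_score(t_rank1, c("f1", "f2"))
  expect_equal(p1$explained_variance_fraction[1], 1, tolerance = 1e-12)
  t_iso <- tibble::tibble(f1 = c(1, 1, -1, -1), f2 = c(1, -1, 1, -1))
  p2 <- pca_compound_score(t_iso, c("f1", "f2"))
  expect_equal(p2$explained_variance_fraction, c(0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(sum(p1$explained_variance_fraction), 1, tolerance = 1e-12)
  # known 1-factor model: recovered PC1 loadings within 0.05 of truth
  microglia3d:::with_seed(42, {
    k <- 6
    w <- rep(1 / sqrt(k), k)
    f <- rnorm(400)
    xmat <- outer(f, w) + matrix(rnorm(400 * k, 0, 0.1), 400, k)
    tb <- tibble::as_tibble(as.data.frame(xmat))
    pf <- pca_compound_score(tb, names(tb))
    l1 <- pf$loadings[, 1]
    sgn <- sign(sum(l1 * w))
    expect_lt(max(abs(sgn * l1 - w)), 0.05)
    # component scores are uncorrelated
    sc <- as.matrix(pf$scores[, paste0("PC", 1:k)])
    cc <- cor(sc)
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  })
  expect_error(pca_compound_score(t_rank1[1:2, ], c("f1", "f2")),
               "at least 3")
})

test_that("PC1 is oriented toward higher ramification", {
  microglia3d:::with_seed(7, {
    seg <- c(rnorm(20, 10), rnorm(20, 2))
    other <- seg * 2 + rnorm(40, 0, 0.5)
    tb <- tibble::tibble("Segments per branch" = seg, other = other)
    p <- pca_compound_score(tb, c("Segments per branch", "other"))
    expect_gt(cor(p$scores$PC1, seg), 0)
  })
})

test_that("rank-sum group test: null, strong separation, monotone invariance", {
  same <- group_test(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_gt(same$p_value, 0.9)
  sep <- group_test(c(1:10, 101:110), rep(c("a", "b"), each = 10))
  expect_lt(sep$p_value, 0.01)
  ref <- stats::wilcox.test(1:10, 101:110, correct = TRUE)
  expect_equal(sep$p_value, ref$p.value)
  v <- c(1, 5, 2, 9, 3, 8, 7, 4)
  lab <- rep(c("a", "b"), 4)
  expect_equal(group_test(v, lab)$statistic,
               group_test(exp(v), lab)$statistic)
})

test_that("manual-vs-automated agreement recovers known correlations", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  ex <- compare_manual(x, x)
  expect_equal(ex$estimate[ex$method == "pearson"], 1, tolerance = 1e-12)
  neg <- compare_manual(x, -x)
  expect_equal(neg$estimate[neg$method == "pearson"], -1, tolerance = 1e-12)
  for (s in 1:10) {
    microglia3d:::with_seed(500 + s, {
      manual <- rnorm(100)
      auto <- 0.8 * manual + sqrt(1 - 0.8^2) * rnorm(100)
      r <- compare_manual(manual, auto)
      est <- r$estimate[r$method == "pearson"]
      expect_gte(est, 0.7)
      expect_lte(est, 0.9)
    })
  }
  expect_error(compare_manual(1:2, 1:2), "at least 3")
})

test_that("tidy/glance/autoplot methods expose the PCA and ROC results", {
  cs <- cached_stack_result()
  ft <- cs$result$features
  labels <- rep(c("g1", "g2"), length.out = nrow(ft))
  scr <- roc_screen(ft, labels = labels)
  expect_s3_class(autoplot(scr), "ggplot")
  sel <- select_features(scr, auc_cutoff = 0)
  p <- pca_compound_score(ft, sel[1:min(3, length(sel))])
  td <- tidy(p)
  expect_true(all(c("feature", "component", "loading") %in% names(td)))
  gl <- glance(p)
  expect_identical(gl$n_cells, nrow(ft))
  expect_s3_class(autoplot(p), "ggplot")
})
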