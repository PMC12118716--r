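test_that("per-peak AUC reproduces hand and brute-force values", {
  fm <- make_fm(cbind(c(1, 2, 3, 4, 5, 6), c(1, 3, 5, 2, 4, 6)))
  lab <- labels_for_fm(fm, grp = c("A", "A", "A", "B", "B", "B"))
  rr <- roc_per_peak(fm, lab, "grp", "A", "B")
  expect_equal(rr$auc[1], 1.0)          # perfect separation
  # identical distributions -> 0.5
  fm2 <- make_fm(cbind(c(1, 2, 3, 1, 2, 3)))
  expect_equal(roc_per_peak(fm2, lab, "grp", "A", "B")$auc, 0.5)
  # A {1,3}, B {2,4} -> 3 of 4 cross pairs favour B
  fm3 <- make_fm(cbind(c(1, 3, 2, 4)))
  lab3 <- labels_for_fm(fm3, grp = c("A", "A", "B", "B"))
  expect_equal(roc_per_peak(fm3, lab3, "grp", "A", "B")$auc, 0.75)
  expect_error(roc_per_peak(fm3, lab3, "grp", "A", "C"), ">= 2 pixels")
})

test_that("AUC is antisymmetric, rank-invariant, and matches standard tools", {
  set.seed(33)
  for (r in 1:5) {
    n_a <- sample(3:30, 1); n_b <- sample(3:30, 1)
    x <- c(round(rnorm(n_a), 1), round(rnorm(n_b, 0.5), 1))  # with ties
    fm <- make_fm(cbind(x))
    lab <- labels_for_fm(fm, grp = rep(c("A", "B"), c(n_a, n_b)))
    ab <- roc_per_peak(fm, lab, "grp", "A", "B")
    ba <- roc_per_peak(fm, lab, "grp", "B", "A")
    expect_equal(ab$auc + ba$auc, 1)
    expect_equal(ab$auc, brute_auc(x[1:n_a], x[-(1:n_a)]))
    # strictly monotone transform leaves the AUC unchanged
    fmt <- make_fm(cbind(exp(x / 2)))
    expect_equal(roc_per_peak(fmt, lab, "grp", "A", "B")$auc, ab$auc)
    # p-value: normal-approximation rank test with tie correction
    w <- suppressWarnings(stats::wilcox.test(
      x[-(1:n_a)], x[1:n_a], exact = FALSE, correct = FALSE))
    expect_equal(ab$p_value, w$p.value, tolerance = 1e-9)
    # independent AUC cross-check
    expect_equal(ab$auc,
                 as.numeric(suppressMessages(pROC::auc(
                   rep(c(0, 1), c(n_a, n_b)), x, direction = "<"))))
  }
})

test_that("candidate selection applies the AUC band and raw p cut", {
  rocs <- data.frame(peak_id = 1:4, mz = 1:4,
                     auc = c(0.66, 0.55, 0.25, 0.70),
                     p_value = c(1e-5, 1e-5, 1e-6, 0.5),
                     q_value = NA, n_a = 10, n_b = 10,
                     direction = "up_in_b", selected = NA)
  sel <- select_candidates(rocs)
  expect_true(sel$selected[1])          # AUC 0.66, p 1e-5
  expect_false(sel$selected[2])         # inside the similarity band
  expect_true(sel$selected[3])          # AUC 0.25, p 1e-6
  expect_false(sel$selected[4])         # band ok but p too large
  expect_error(select_candidates(rocs, auc_hi = 0.4, auc_lo = 0.6),
               "auc_lo < auc_hi")
})

test_that("protein assignment enforces tolerance, tie-breaks and the 2-peptide rule", {
  peaks <- peak_table(c(1477.80, 1490.00, 1505.30),
                      c(1477.4, 1489.6, 1504.9),
                      c(1478.2, 1490.4, 1505.7))
  pep <- data.frame(
    sequence = c("PEPA", "PEPB", "PEPC", "PEPD", "PEPE"),
    mz = c(1477.76, 1489.95, 1505.25, 1477.95, 1600.0),
    accession = c("P1", "P1", "P2", "P3", "P4"),
    protein_name = c("prot1", "prot1", "prot2", "prot3", "prot4"),
    score = c(30, 40, 25, 20, 90))
  res <- assign_proteins(peaks, pep, tol_da = 0.15)
  a <- res$assignments
  expect_equal(a$sequence[a$peak_id == 1], "PEPA")  # delta 0.04 < 0.15
  expect_equal(a$delta_da[a$peak_id == 1], 0.04, tolerance = 1e-9)
  # P1 has two distinct peaks x two distinct peptides -> identified
  expect_true(res$proteins$identified[res$proteins$accession == "P1"])
  # single-peptide proteins are never identified
  expect_false(res$proteins$identified[res$proteins$accession == "P2"])
  expect_false("P4" %in% res$proteins$accession)

  # delta exactly at the tolerance is rejected (strict <)
  pk2 <- peak_table(1000.15, 999.75, 1000.55)
  pepx <- data.frame(sequence = "X", mz = 1000.00, accession = "PX",
                     protein_name = "x", score = 50)
  expect_equal(nrow(assign_proteins(pk2, pepx)$assignments), 0)

  # equal delta: the higher score wins
  pk3 <- peak_table(1000.00, 999.6, 1000.4)
  pept <- data.frame(sequence = c("LO", "HI"), mz = c(999.95, 1000.05),
                     accession = c("A", "B"), protein_name = c("a", "b"),
                     score = c(20, 35))
  expect_equal(assign_proteins(pk3, pept)$assignments$sequence, "HI")

  # input order is irrelevant
  res2 <- assign_proteins(peaks, pep[sample(5), ])
  expect_equal(res2$assignments, res$assignments)
  expect_error(assign_proteins(peaks, pep[0, ]), "empty")
})

test_that("a protein is not identified when one peak carries both its peptides", {
  pk <- peak_table(1000.00, 999.6, 1000.4)
  pep <- data.frame(sequence = c("S1", "S2"), mz = c(999.99, 1000.05),
                    accession = "P", protein_name = "p", score = c(50, 40))
  res <- assign_proteins(pk, pep)
  expect_equal(res$proteins$n_peaks, 1)
  expect_false(res$proteins$identified)
})

test_that("PCA ratios equal covariance eigenvalues and signs are deterministic", {
  set.seed(44)
  X <- matrix(rnorm(60 * 5), 60, 5) %*% diag(c(5, 3, 2, 1, 0.5))
  fm <- make_fm(X)
  pca <- pca_on_candidates(fm)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(pca$explained_variance_ratio, ev / sum(ev), tolerance = 1e-9)
  expect_true(all(diff(pca$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pca$explained_variance_ratio), 1 + 1e-12)
  # sign convention: the largest-magnitude loading is positive
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)

  # pixels on a line -> PC1 explains everything
  t_ <- rnorm(30)
  fm2 <- make_fm(cbind(2 * t_, -t_, 0.5 * t_))
  p2 <- pca_on_candidates(fm2)
  expect_equal(p2$explained_variance_ratio[1], 1, tolerance = 1e-12)

  expect_error(pca_on_candidates(make_fm(matrix(3, 10, 3))), "rank-0")
  expect_error(pca_on_candidates(make_fm(X[, 1, drop = FALSE])), ">= 2")
})

test_that("PC score images map scores back to pixels", {
  set.seed(45)
  fm <- make_fm(matrix(rnorm(40), 10, 4))
  pca <- pca_on_candidates(fm)
  im <- pc_score_image(pca, 2)
  expect_equal(im$value, unname(pca$scores[, 2]))
  expect_equal(im$ix, fm$pixel_index$ix)
})

test_that("two-way ANOVA matches hand-computed sums of squares on a balanced design", {
  # balanced 2x2, n = 3 per cell
  d <- data.frame(
    group = rep(c("L", "R"), each = 6),
    class = rep(rep(c("c", "o"), each = 3), 2),
    percent = c(10, 12, 11, 20, 22, 21, 13, 15, 14, 29, 31, 30))
  out <- compare_area_groups(d)
  # textbook SS from cell/marginal means
  g <- mean(d$percent)
  mg <- tapply(d$percent, d$group, mean)
  mc <- tapply(d$percent, d$class, mean)
  mcell <- tapply(d$percent, interaction(d$group, d$class), mean)
  ss_a <- 6 * sum((mg - g)^2)
  ss_b <- 6 * sum((mc - g)^2)
  ss_cells <- 3 * sum((mcell - g)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((d$percent - rep(mcell[interaction(d$group, d$class)],
                               1))^2)
  expect_equal(out$sum_sq[out$term == "group"], ss_a, tolerance = 1e-9)
  expect_equal(out$sum_sq[out$term == "class"], ss_b, tolerance = 1e-9)
  expect_equal(out$sum_sq[out$term == "group:class"], ss_ab,
               tolerance = 1e-9)
  expect_equal(out$sum_sq[out$term == "residuals"], ss_e, tolerance = 1e-9)
  f_b <- (ss_b / 1) / (ss_e / 8)
  expect_equal(out$statistic[out$term == "class"], f_b, tolerance = 1e-9)
  expect_equal(out$p_value[out$term == "class"],
               stats::pf(f_b, 1, 8, lower.tail = FALSE), tolerance = 1e-9)

  expect_error(compare_area_groups(d[-(1:2), ]), ">= 2 samples")
})

test_that("a planted class effect is detected with high power", {
  set.seed(77)
  hits <- 0
  for (r in 1:200) {
    d <- data.frame(group = rep(c("L", "R"), each = 14),
                    class = rep(rep(c("c", "o"), each = 7), 2),
                    percent = rnorm(28))
    d$percent[d$class == "o"] <- d$percent[d$class == "o"] + 3  # 3 SD shift
    p <- compare_area_groups(d)$p_value
    hits <- hits + (p[2] < 0.05)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("all-null two-way design yields large p-values (fixed seed)", {
  set.seed(1234)
  d <- data.frame(group = rep(c("L", "R"), each = 8),
                  class = rep(rep(c("c", "o"), each = 4), 2),
                  percent = rnorm(16))
  p <- compare_area_groups(d)$p_value[1:3]
  expect_true(all(p > 0.05))
})
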