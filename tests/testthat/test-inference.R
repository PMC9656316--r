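chisq_2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("chi-square cross-table matches the closed-form oracle", {
  # homogeneous table
  h <- chisq_crosstable(matrix(10, 2, 2))
  expect_equal(h$statistic, 0)
  expect_equal(h$p.value, 1)
  # textbook 2x2: 60 * (400 - 100)^2 / 30^4 = 6.6667
  x <- chisq_crosstable(matrix(c(20, 10, 10, 20), 2, 2))
  expect_equal(x$statistic, chisq_2x2_oracle(20, 10, 10, 20),
               tolerance = 1e-9)
  expect_equal(x$statistic, 20 / 3, tolerance = 1e-9)
  expect_identical(x$df, 1L)
  # property: closed form on random 2x2 tables
  set.seed(4)
  for (i in 1:20) {
    t2 <- matrix(sample(1:50, 4), 2, 2)
    expect_equal(chisq_crosstable(t2)$statistic,
                 chisq_2x2_oracle(t2[1, 1], t2[1, 2], t2[2, 1], t2[2, 2]),
                 tolerance = 1e-9)
  }
  # doubling all cells doubles the statistic and shrinks p
  d <- chisq_crosstable(2 * matrix(c(20, 10, 10, 20), 2, 2))
  expect_equal(d$statistic, 2 * x$statistic, tolerance = 1e-9)
  expect_lt(d$p.value, x$p.value)
  # wider tables: df = (r-1)(k-1)
  w <- chisq_crosstable(matrix(c(5, 6, 7, 8, 9, 10), 2, 3))
  expect_identical(w$df, 2L)
  # low-expected flag
  expect_true(chisq_crosstable(matrix(c(1, 0, 0, 30), 2, 2))$low_expected)
  expect_error(chisq_crosstable(matrix(c(0, 0, 5, 5), 2, 2)), "positive")
})

test_that("two-sample t matches stats::t.test to 1e-10", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(2.0, 2.5, 6.1, 3.3)
  for (ve in c(FALSE, TRUE)) {
    ours <- two_sample_t(x, y, var_equal = ve)
    ref <- stats::t.test(x, y, var.equal = ve)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
  # identical samples
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p.value, 1)
  # clear separation
  sep <- two_sample_t(c(1, 2, 3), c(11, 12, 13))
  expect_gt(abs(sep$t), 5)
  expect_lt(sep$p.value, 0.01)
  # zero variance in both samples, equal means -> p = 1 convention
  zz <- two_sample_t(c(2, 2, 2), c(2, 2))
  expect_equal(zz$p.value, 1)
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("coefficient of variation is sd/mean, scale invariant, errors on zero mean", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2,
               tolerance = 1e-12)
  x <- c(2, 4, 9, 3)
  expect_equal(coefficient_of_variation(7.3 * x),
               coefficient_of_variation(x), tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("average-linkage correlation clustering behaves on planted structure", {
  set.seed(7)
  base_a <- sin(seq_len(20)); base_b <- cos(seq_len(20))
  m <- rbind(a1 = base_a + rnorm(20, sd = 0.01),
             a2 = base_a + rnorm(20, sd = 0.01),
             b1 = base_b + rnorm(20, sd = 0.01),
             b2 = base_b + rnorm(20, sd = 0.01))
  dend <- cluster_profiles(m)
  # first two merges join within-group pairs (singleton-singleton merges)
  first2 <- dend$hclust$merge[1:2, ]
  labs <- dend$hclust$labels
  joined <- apply(first2, 1, function(r) paste(sort(substr(labs[-r], 1, 1)), collapse = ""))
  expect_true(all(joined %in% c("aa", "bb")))
  # heights are non-decreasing and the similarity scale maps 100*(1 - d/2)
  expect_true(all(diff(dend$hclust$height) >= -1e-12))
  expect_equal(dend$similarity_heights,
               100 * (1 - dend$distance_heights / 2))
  # identical rows merge at distance 0
  m2 <- rbind(x = base_a, y = base_a, z = base_b)
  expect_equal(cluster_profiles(m2)$hclust$height[1], 0, tolerance = 1e-12)
  # permutation leaves merge heights unchanged
  perm <- m[c(3, 1, 4, 2), ]
  expect_equal(sort(cluster_profiles(perm)$hclust$height),
               sort(dend$hclust$height), tolerance = 1e-12)
  # constant rows are rejected by name
  expect_error(cluster_profiles(rbind(k = rep(1, 5), l = 1:5)), "k")
  # newick export parses back to the same number of tips
  expect_identical(length(ape::read.tree(text = dend$newick)$tip.label), 4L)
})

test_that("missing-value columns are dropped with a notice before clustering", {
  m <- rbind(a = c(1, 2, NA, 4), b = c(2, 1, 5, 3), c = c(5, 1, 2, 8))
  expect_message(dend <- cluster_profiles(m), "dropping 1")
  expect_identical(dend$n_features, 3L)
})

test_that("PCA scores follow the deterministic sign convention and variance partition", {
  set.seed(11)
  g1 <- matrix(rnorm(30, mean = 0), 3, 10)
  g2 <- matrix(rnorm(30, mean = 2), 3, 10)
  m <- rbind(g1, g2)
  rownames(m) <- paste0("s", 1:6)
  p <- pca_scores(m)
  expect_identical(p$n_components, 2L)
  expect_true(all(p$var_explained >= 0))
  expect_lte(sum(p$var_explained[1:2]), 1 + 1e-12)
  # sign convention: largest-magnitude loading positive per component
  for (j in 1:2) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  # planted groups separate along PC1
  gap <- abs(mean(p$scores[1:3, 1]) - mean(p$scores[4:6, 1]))
  spread <- max(stats::sd(p$scores[1:3, 1]), stats::sd(p$scores[4:6, 1]))
  expect_gt(gap, spread)
  # rank-1 data: PC2 variance fraction 0
  line <- outer(c(1, 2, 3, 4), seq_len(8))
  rownames(line) <- paste0("r", 1:4)
  pl <- suppressMessages(pca_scores(line))
  expect_equal(pl$var_explained[2], 0, tolerance = 1e-12)
  # rank-2 reconstruction from scores and loadings to 1e-9
  rank2 <- outer(c(1, 2, 3, 5), seq_len(6)) +
    outer(c(0, 1, 0, 1), rep(c(1, -1), 3))
  rownames(rank2) <- paste0("q", 1:4)
  p2 <- pca_scores(rank2)
  centered <- sweep(rank2, 2, colMeans(rank2))
  recon <- p2$scores %*% t(p2$loadings)
  expect_equal(unname(recon), unname(centered), tolerance = 1e-9)
})
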