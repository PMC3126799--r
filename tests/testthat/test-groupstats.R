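test_that("exact signed-rank p-values match hand values and enumeration", {
  # nine positive differences: one-sided p = 1/2^9
  w <- wilcoxonSignedRank(rep(1, 9) + (1:9) / 100)
  expect_equal(w$p.greater, 1 / 512)
  expect_equal(w$statistic, 45)
  # antisymmetric sample is exactly central: two-sided p = 1
  w2 <- wilcoxonSignedRank(c(-3, -1, 1, 3))
  expect_equal(w2$p.two.sided, 1)
  # all-zero differences degenerate with warning
  expect_warning(w3 <- wilcoxonSignedRank(rep(2, 5), rep(2, 5)), "zero")
  expect_equal(w3$p.two.sided, 1)
  # full 2^n enumeration oracle, with and without ties
  set.seed(60)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    d <- sample(c(-4:-1, 1:5), n, replace = TRUE) +
      ifelse(rep %% 2 == 0, 0, rnorm(n, sd = 0.01))
    got <- wilcoxonSignedRank(d)
    ref <- bruteWilcoxon(d)
    expect_equal(got$statistic, ref$statistic)
    expect_equal(got$p.greater, ref$greater, tolerance = 1e-12)
    expect_equal(got$p.less, ref$less, tolerance = 1e-12)
    expect_equal(got$p.two.sided, ref$two, tolerance = 1e-12)
  }
})

test_that("exact signed-rank agrees with wilcox.test on tie-free data", {
  set.seed(61)
  x <- rnorm(10); y <- rnorm(10)
  got <- wilcoxonSignedRank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(got$p.two.sided, ref$p.value, tolerance = 1e-12)
  refg <- wilcox.test(x, y, paired = TRUE, exact = TRUE,
                      alternative = "greater")
  expect_equal(got$p.greater, refg$p.value, tolerance = 1e-12)
})

test_that("large-sample path returns a sane normal approximation", {
  set.seed(62)
  d <- rnorm(40, mean = 0.3)
  got <- wilcoxonSignedRank(d)
  expect_equal(got$method, "normal approximation")
  ref <- wilcox.test(d, correct = TRUE, exact = FALSE)
  expect_equal(got$p.two.sided, ref$p.value, tolerance = 1e-6)
})

test_that("paired t matches the closed form and flags degeneracy", {
  x <- c(12, 14, 11, 15, 13); y <- c(10, 13, 12, 11, 10)
  d <- x - y
  got <- pairedT(x, y)
  expect_equal(got$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_error(pairedT(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  z <- c(1, -1, 2, -2)
  expect_equal(pairedT(z, numeric(4))$statistic, 0)
  expect_equal(pairedT(z, numeric(4))$p.two.sided, 1)
})

test_that("repeated-measures ANOVA matches the SS decomposition oracle", {
  # identical columns plus subject offsets: F = 0
  subj <- rnorm(6)
  mat0 <- matrix(subj, 6, 4)
  expect_equal(rmAnova(mat0)$F, 0)
  # random toy tables against the hand decomposition
  set.seed(63)
  for (rep in 1:5) {
    mat <- matrix(rnorm(9 * 4, mean = rep(c(0, 1, 0.5, 2), each = 9)), 9, 4)
    an <- rmAnova(mat)
    expect_equal(an$F, bruteRmAnovaF(mat), tolerance = 1e-10)
    expect_equal(c(an$df1, an$df2), c(3, 24))
  }
  m3 <- matrix(c(1, 2, 3, 2, 3, 4, 4, 5, 7), 3, 3)
  expect_equal(rmAnova(m3)$F, bruteRmAnovaF(m3), tolerance = 1e-10)
  mat <- matrix(rnorm(12), 3, 4); mat[2, 2] <- NA
  expect_error(rmAnova(mat), "missing")
})

test_that("pairwise comparisons apply the step-down adjustment", {
  set.seed(64)
  mat <- matrix(rnorm(8 * 2), 8, 2)
  one <- multipleComparisons(mat)
  expect_equal(one$p.adjusted, one$p.raw)     # single pair: no adjustment
  mat4 <- matrix(rnorm(8 * 4), 8, 4)
  mc <- multipleComparisons(mat4)
  expect_equal(nrow(mc), 6L)
  expect_equal(mc$p.adjusted, p.adjust(mc$p.raw, "holm"))
  expect_true(all(mc$p.adjusted >= mc$p.raw - 1e-15))
  # identical columns are never significant
  same <- matrix(rnorm(8), 8, 4)
  suppressWarnings(
    expect_true(all(multipleComparisons(same, test = "wilcoxon")$p.adjusted ==
                      1)))
})
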