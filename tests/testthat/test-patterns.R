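test_that("pattern extraction picks the designated rows", {
  d <- tinyDesign()
  ev <- buildEventTable(d, seed = 5)
  part <- partitionByCondition(ev, d)
  values <- matrix(seq_len(totalSamples(d) * 3), totalSamples(d), 3)
  ti <- trialInfo(part, "speech")
  for (t in c(1L, 4L)) {
    ps <- extractPatterns(values, c(1L, 3L), part, "speech", t)
    expect_equal(patternMatrix(ps),
                 values[ti$start_row + (t - 1L), c(1, 3)])
    expect_equal(ps@category, ti$category)
  }
  expect_error(extractPatterns(values, 1:2, part, "speech", 9L), "t must")
  # fold restriction yields whole balanced trials
  ps1 <- extractPatterns(values, 1:2, part, "speech", 2L, fold = 1)
  expect_equal(nrow(patternMatrix(ps1)), 2L)
  expect_setequal(ps1@category, c("old", "young"))
})

test_that("reproducibility index matches hand values and the brute oracle", {
  expect_equal(reproducibilityIndex(rbind(c(1, 2), c(2, 4), c(0.5, 1))), 1)
  expect_equal(reproducibilityIndex(rbind(c(1, 0), c(0, 1))), 0)
  X <- rbind(c(1, 0), c(1, 1), c(0, 1))
  expect_equal(reproducibilityIndex(X), (sqrt(2) / 2 + sqrt(2) / 2 + 0) / 3,
               tolerance = 1e-12)
  set.seed(40)
  for (rep in 1:10) {
    n <- sample(3:50, 1); p <- sample(2:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    expect_equal(reproducibilityIndex(X), bruteReproducibility(X),
                 tolerance = 1e-12)
  }
})

test_that("reproducibility index is invariant to order, scale and rotation", {
  set.seed(41)
  X <- matrix(rnorm(10 * 6), 10, 6)
  R <- reproducibilityIndex(X)
  expect_equal(reproducibilityIndex(X[sample(10), ]), R, tolerance = 1e-12)
  expect_equal(reproducibilityIndex(X * runif(10, 0.1, 5)), R,
               tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(reproducibilityIndex(X %*% Q), R, tolerance = 1e-10)
  # zero-norm pattern errors and names the trial
  X[3, ] <- 0
  expect_error(reproducibilityIndex(X), "trial\\(s\\) 3")
})

test_that("mean-angle variant preserves pairwise ordering", {
  set.seed(42)
  tight <- matrix(rnorm(8 * 5, mean = 3), 8, 5)
  loose <- matrix(rnorm(8 * 5, mean = 0.3), 8, 5)
  expect_gt(reproducibilityIndex(tight, "mean-angle"),
            reproducibilityIndex(loose, "mean-angle"))
  expect_gt(reproducibilityIndex(tight), reproducibilityIndex(loose))
})

test_that("average norm matches hand computation and homogeneity", {
  expect_equal(averageNorm(rbind(c(1, 0), c(0, -1))), 1)
  expect_equal(averageNorm(rbind(c(3, 4), c(0, 0))), 2.5)
  set.seed(43)
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(averageNorm(X), bruteAverageNorm(X), tolerance = 1e-12)
  expect_equal(averageNorm(3 * X), 3 * averageNorm(X), tolerance = 1e-12)
  expect_equal(reproducibilityIndex(3 * X), reproducibilityIndex(X),
               tolerance = 1e-12)
})

test_that("difference patterns subtract the baseline per trial", {
  d <- tinyDesign()
  ev <- buildEventTable(d, seed = 6)
  part <- partitionByCondition(ev, d)
  set.seed(44)
  values <- matrix(rnorm(totalSamples(d) * 4), totalSamples(d), 4)
  base <- extractPatterns(values, 1:4, part, "picture", 1L)
  p3 <- extractPatterns(values, 1:4, part, "picture", 3L)
  dp <- differencePatterns(p3, base)
  expect_equal(patternMatrix(dp), patternMatrix(p3) - patternMatrix(base))
  expect_equal(unname(averageNorm(differencePatterns(base, base))),
               c(0, 0))
  # trial mismatch errors
  other <- extractPatterns(values, 1:4, part, "speech", 1L)
  expect_error(differencePatterns(p3, other), "trials")
})

test_that("PatternSet statistics are computed per category", {
  d <- tinyDesign()
  ev <- buildEventTable(d, seed = 7)
  part <- partitionByCondition(ev, d)
  set.seed(45)
  values <- matrix(rnorm(totalSamples(d) * 4), totalSamples(d), 4)
  ps <- extractPatterns(values, 1:4, part, "congruent", 2L)
  R <- reproducibilityIndex(ps)
  expect_named(R, c("old", "young"))
  X <- patternMatrix(ps)
  expect_equal(unname(R["old"]),
               bruteReproducibility(X[ps@category == "old", ]),
               tolerance = 1e-12)
})
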