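test_that("correlation screening ranks stimulus-locked voxels first", {
  d <- ExperimentDesign()
  ev <- buildEventTable(d, seed = 1)
  reg <- boldRegressors(ev, d)
  hs <- simulatedBold(reg)[1:100]
  set.seed(20)
  X <- cbind(hs, -hs, matrix(rnorm(100 * 8), 100, 8))
  act <- selectActivated(X, hs, k = 2)
  expect_equal(abs(act$r[1]), 1, tolerance = 1e-12)
  expect_equal(abs(act$r[2]), 1, tolerance = 1e-12)
  expect_setequal(act$activated, 1:2)
  # a noisy copy among permuted noise ranks first
  X2 <- cbind(matrix(rnorm(100 * 9), 100, 9), hs + rnorm(100, sd = 0.3))
  expect_equal(selectActivated(X2, hs, k = 1)$activated, 10L)
  # zero-variance voxels get r = 0
  X3 <- cbind(hs, 0)
  expect_equal(selectActivated(X3, hs, k = 1)$r[2], 0)
  expect_error(selectActivated(X3, hs, k = 5), "exceeds")
})

test_that("sparse selection finds a planted regressor-matching voxel", {
  d <- ExperimentDesign()
  ev <- buildEventTable(d, seed = 2)
  reg <- boldRegressors(ev, d)
  part <- partitionByCondition(ev, d)
  rows <- foldRows(part, "congruent", 1, "train")
  hl <- labeledBold(reg)[rows]
  wins <- 0L
  for (seed in 1:10) {
    set.seed(100 + seed)
    X <- matrix(rnorm(300 * 30), 300, 30)
    planted <- sample(30, 1)
    X[, planted] <- hl + rnorm(300, sd = 0.05)
    sel <- sparseSelect(X, hl, k = 3, nRounds = 40L, subsetSize = 10L,
                        seed = seed)
    wins <- wins + (which.max(sel@weights) == planted)
  }
  expect_equal(wins, 10L)
})

test_that("sparse selection is deterministic and permutation-equivariant", {
  d <- ExperimentDesign()
  ev <- buildEventTable(d, seed = 3)
  reg <- boldRegressors(ev, d)
  part <- partitionByCondition(ev, d)
  rows <- foldRows(part, "picture", 2, "train")
  hl <- labeledBold(reg)[rows]
  set.seed(30)
  X <- matrix(rnorm(300 * 20), 300, 20)
  X[, 4] <- hl + rnorm(300, sd = 0.1)
  s1 <- sparseSelect(X, hl, k = 5, nRounds = 30L, subsetSize = 8L, seed = 7)
  s2 <- sparseSelect(X, hl, k = 5, nRounds = 30L, subsetSize = 8L, seed = 7)
  expect_identical(selectedVoxels(s1), selectedVoxels(s2))
  expect_identical(s1@weights, s2@weights)
  # relabeling voxel ids relabels the result consistently: the same columns
  # under new global ids select the same columns, reported under those ids
  ids <- 101:120
  s3 <- sparseSelect(X, hl, k = 5, nRounds = 30L, subsetSize = 8L, seed = 7,
                     voxelIds = ids)
  expect_identical(selectedVoxels(s3), ids[selectedVoxels(s1)])
  expect_identical(s3@weights, s1@weights)
})

test_that("degenerate selection inputs are rejected", {
  X <- matrix(rnorm(60), 20, 3)
  expect_error(sparseSelect(X, numeric(20), k = 2, nRounds = 5,
                            subsetSize = 2), "zero")
  expect_error(sparseSelect(X, rnorm(20), k = 2, nRounds = 5,
                            subsetSize = 9), "subsetSize")
})
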