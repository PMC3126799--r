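test_that("linear SVM separates separable classes and memorizes training", {
  set.seed(50)
  x <- rbind(matrix(rnorm(40, mean = 2), 10, 4),
             matrix(rnorm(40, mean = -2), 10, 4))
  y <- factor(rep(c("old", "young"), each = 10))
  train <- list(x = x, y = y)
  fit <- trainAndPredict(train, train)
  expect_equal(fit$accuracy, 100)
  expect_equal(fit$nTest, 20L)
  # single-class training errors
  expect_error(trainAndPredict(list(x = x, y = factor(rep("old", 20),
                                                      levels = levels(y))),
                               train), "both categories")
})

test_that("label-permuted decoding sits at chance", {
  set.seed(51)
  accs <- replicate(100, {
    x <- matrix(rnorm(40 * 10), 40, 10)
    y <- factor(rep(c("old", "young"), 20))
    tr <- list(x = x[1:30, ], y = y[1:30])
    te <- list(x = x[31:40, ], y = y[31:40])
    trainAndPredict(tr, te)$accuracy
  })
  expect_lt(abs(mean(accs) - 50), 3)
})

test_that("normalized features have unit length and leave labels intact", {
  run <- deskRun()
  pre <- preprocessDataset(run$ds)
  values <- boldMatrix(pre)
  part <- partitionByCondition(eventTable(run$ds), experimentDesign(run$ds))
  vox <- selectedVoxels(run$res$selections[[1]])
  f <- makeFeatures(values, vox, part, "congruent", 1, "train", t = 4L,
                    normalize = TRUE)
  expect_equal(unname(sqrt(rowSums(f$x^2))), rep(1, nrow(f$x)))
  expect_equal(nrow(f$x), 60L)           # 3 training folds x 20 trials
  ft <- makeFeatures(values, vox, part, "congruent", 1, "test", t = 4L)
  expect_equal(nrow(ft$x), 20L)
  expect_equal(as.integer(table(ft$y)), c(10L, 10L))
})

test_that("the decoding grid covers all selection/test condition pairs", {
  run <- deskRun()
  dec <- run$res$decoding
  expect_equal(nrow(dec), 2 * 4 * 4 * 4)   # variants x selections x folds x tests
  expect_true(all(dec$accuracy >= 0 & dec$accuracy <= 100))
  expect_true(all(dec$n_test == 20L))
  expect_true(all(dec$n_pred_first + dec$n_pred_second == dec$n_test))
  agg <- averageAcrossFolds(run$res)$decoding
  expect_equal(nrow(agg), 2 * 16)
})

test_that("raw and normalized variants agree on scale-homogeneous data", {
  run <- deskRun()
  agg <- averageAcrossFolds(run$res)$decoding
  raw <- agg$accuracy[agg$variant == "raw"]
  nrm <- agg$accuracy[agg$variant == "normalized"]
  expect_lt(mean(abs(raw - nrm)), 5)
})

test_that("the trained model ignores test-fold content", {
  run <- deskRun()
  pre <- preprocessDataset(run$ds)
  values <- boldMatrix(pre)
  part <- partitionByCondition(eventTable(run$ds), experimentDesign(run$ds))
  vox <- selectedVoxels(run$res$selections[[1]])
  tr <- makeFeatures(values, vox, part, "congruent", 1, "train", t = 4L)
  te <- makeFeatures(values, vox, part, "congruent", 1, "test", t = 4L)
  p1 <- trainAndPredict(tr, te)
  teperm <- te; teperm$y <- sample(te$y)
  p2 <- trainAndPredict(tr, teperm)
  expect_identical(p1$predictions, p2$predictions)
  expect_identical(p1$decisionValues, p2$decisionValues)
})
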