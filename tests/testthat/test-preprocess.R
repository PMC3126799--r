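test_that("per-run z-scoring uses population variance and handles constants", {
  x <- matrix(c(1, 2, 3), 3, 1)
  attr(x, "run") <- rep(1L, 3)
  z <- zscoreRuns(x)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # idempotence
  expect_equal(unclass(zscoreRuns(z))[, 1], z[, 1], tolerance = 1e-12)
  # constant voxel maps to zero with a warning
  cst <- matrix(5, 4, 1)
  expect_warning(z2 <- zscoreRuns(cst), "constant")
  expect_equal(as.numeric(z2), rep(0, 4))
})

test_that("per-run detrending removes exactly the least-squares line", {
  x <- matrix(2 * (1:10) + 3, 10, 1)
  expect_equal(as.numeric(detrendRuns(x)), rep(0, 10), tolerance = 1e-10)
  # zero-mean sinusoid: result equals subtracting its own fitted line
  set.seed(2)
  v <- sin(seq(0, 6 * pi, length.out = 20)) + rnorm(20, sd = 0.1)
  fit <- lm.fit(cbind(1, 1:20), v)
  got <- as.numeric(detrendRuns(matrix(v, 20, 1)))
  expect_equal(got, unname(fit$residuals), tolerance = 1e-10)
  # residuals orthogonal to intercept and time
  expect_lt(abs(sum(got)), 1e-8)
  expect_lt(abs(sum(got * (1:20))), 1e-8)
  # detrend is idempotent
  expect_equal(as.numeric(detrendRuns(matrix(got, 20, 1))), got,
               tolerance = 1e-10)
})

test_that("neither preprocessing step mixes runs", {
  set.seed(3)
  x <- matrix(rnorm(40), 20, 2)
  run <- rep(1:2, each = 10)
  attr(x, "run") <- run
  zc <- zscoreRuns(x)
  z1 <- zscoreRuns(x[run == 1, , drop = FALSE])
  z2 <- zscoreRuns(x[run == 2, , drop = FALSE])
  expect_equal(unclass(zc)[run == 1, ], unclass(z1), ignore_attr = TRUE)
  expect_equal(unclass(zc)[run == 2, ], unclass(z2), ignore_attr = TRUE)
  dc <- detrendRuns(x)
  d1 <- detrendRuns(x[run == 1, , drop = FALSE])
  expect_equal(unclass(dc)[run == 1, ], unclass(d1), ignore_attr = TRUE)
})

test_that("masking restricts columns and validates ids", {
  set.seed(4)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(applyMask(x, 1:4), x, ignore_attr = TRUE)
  expect_equal(ncol(applyMask(x, 2L)), 1L)
  expect_error(applyMask(x, integer(0)), "empty")
  expect_error(applyMask(x, 9L), "unknown")
})

test_that("FmriExperiment preprocessing matches the matrix operations", {
  d <- tinyDesign()
  cfg <- syntheticConfig(nVoxels = 30L, nInformative = 4L, nRoiPerSide = 2L,
                         seed = 6, design = d)
  ds <- generateSubject(cfg, d)
  values <- boldMatrix(ds)
  attr(values, "run") <- runIds(ds)
  pre <- preprocessDataset(ds)
  expect_s4_class(pre, "FmriExperiment")
  expect_equal(boldMatrix(pre),
               unclass(detrendRuns(zscoreRuns(values))),
               ignore_attr = TRUE, tolerance = 1e-12)
  m <- applyMask(ds, 1:10)
  expect_equal(nrow(m), 10L)
  expect_error(applyMask(ds, 10000L), "unknown")
})
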