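test_that("generated subjects have the designed dimensions and metadata", {
  run <- deskRun()
  ds <- run$ds
  expect_s4_class(ds, "FmriExperiment")
  expect_equal(ncol(ds), 1600L)                 # samples
  expect_equal(nrow(ds), run$proto$config@nVoxels)
  ev <- eventTable(ds)
  expect_equal(nrow(ev), 320L)
  expect_length(informativeVoxels(ds), 60L)
  coords <- voxelCoords(ds)
  rois <- stsMtgRois()
  inf <- informativeVoxels(ds)
  expect_equal(sum(inRoiCube(coords[inf, ], rois$left)), 30L)
  expect_equal(sum(inRoiCube(coords[inf, ], rois$right)), 30L)
  # non-informative voxels stay outside both cubes
  outside <- setdiff(seq_len(nrow(ds)), inf)
  expect_false(any(inRoiCube(coords[outside, ], rois$left) |
                     inRoiCube(coords[outside, ], rois$right)))
})

test_that("generation is deterministic and cohorts are independent", {
  d <- tinyDesign()
  cfg <- syntheticConfig(nVoxels = 40L, nInformative = 8L, nRoiPerSide = 4L,
                         seed = 77, design = d)
  a <- generateSubject(cfg, d)
  b <- generateSubject(cfg, d)
  expect_identical(boldMatrix(a), boldMatrix(b))
  expect_identical(eventTable(a), eventTable(b))
  cohort <- generateCohort(cfg, nSubjects = 3L, design = d)
  expect_length(cohort, 3L)
  expect_false(identical(boldMatrix(cohort[[1]]), boldMatrix(cohort[[2]])))
  expect_false(identical(boldMatrix(cohort[[2]]), boldMatrix(cohort[[3]])))
  cohort2 <- generateCohort(cfg, nSubjects = 3L, design = d)
  expect_identical(boldMatrix(cohort[[2]]), boldMatrix(cohort2[[2]]))
})

test_that("without planted effects the category-conditional means coincide", {
  d <- tinyDesign()
  cfg <- syntheticConfig(nVoxels = 30L, nInformative = 6L, nRoiPerSide = 3L,
                         categoryAmplitude = 0, noiseSd = 0, driftSd = 0,
                         withinClassDispersion = 0, seed = 3, design = d)
  ds <- generateSubject(cfg, d)
  values <- boldMatrix(ds)
  part <- partitionByCondition(eventTable(ds), d)
  for (cc in conditionNames(d)) {
    ps <- extractPatterns(values, seq_len(30), part, cc, 4L)
    X <- patternMatrix(ps)
    mo <- colMeans(X[ps@category == "old", , drop = FALSE])
    my <- colMeans(X[ps@category == "young", , drop = FALSE])
    expect_equal(mo, my, tolerance = 1e-12)
  }
})

test_that("stronger planted effects do not decrease decoding accuracy", {
  d <- ExperimentDesign()
  accs <- sapply(c(0, 1.6), function(beta) {
    out <- c()
    for (seed in 1:3) {
      p <- deskScaleProtocol(seed = seed, categoryAmplitude = beta)
      ds <- generateSubject(p$config, p$design)
      pre <- preprocessDataset(ds)
      values <- boldMatrix(pre)
      part <- partitionByCondition(eventTable(ds), p$design)
      reg <- boldRegressors(eventTable(ds), p$design)
      sel <- runSelection(values, reg, part, "congruent", 1, p$params,
                          seed = seed)
      tr <- makeFeatures(values, selectedVoxels(sel), part, "congruent", 1,
                         "train", t = 4L)
      te <- makeFeatures(values, selectedVoxels(sel), part, "congruent", 1,
                         "test", t = 4L)
      out <- c(out, trainAndPredict(tr, te)$accuracy)
    }
    mean(out)
  })
  expect_gt(accs[2], accs[1])
  expect_lt(abs(accs[1] - 50), 15)   # null sits near chance per-fold
})
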