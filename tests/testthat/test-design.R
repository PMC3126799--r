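test_that("design invariants hold for the reference and smaller designs", {
  d <- ExperimentDesign()
  expect_equal(totalSamples(d), 1600L)
  expect_equal(samplesPerTrial(d), 5L)
  td <- tinyDesign()
  expect_equal(totalSamples(td),
               td@runs * (td@trialsPerCondition * td@conditionsPerRun) *
                 samplesPerTrial(td))
  expect_error(ExperimentDesign(trialsPerCondition = 10), "multiple")
  expect_error(ExperimentDesign(trialDuration = 9), "divisible")
})

test_that("schedules are balanced within conditions and fold blocks", {
  d <- ExperimentDesign()
  ev <- buildEventTable(d, seed = 3)
  expect_equal(nrow(ev), 320L)
  expect_true(all(table(ev$condition) == 80L))
  for (cc in conditionNames(d)) {
    e <- ev[ev$condition == cc, ]
    e <- e[order(e$run, e$onset), ]
    expect_equal(as.integer(table(e$category)), c(40L, 40L))
    # every contiguous block of 20 trials is category-balanced
    blocks <- split(e$category, rep(1:4, each = 20))
    for (b in blocks) expect_equal(sum(b == "old"), 10L)
  }
  # onsets strictly increasing, no overlap
  expect_silent(validateEvents(ev, d))
  # determinism
  expect_identical(ev, buildEventTable(d, seed = 3))
  expect_false(identical(ev, buildEventTable(d, seed = 4)))
})

test_that("event validation rejects malformed schedules", {
  d <- ExperimentDesign()
  ev <- buildEventTable(d, seed = 1)
  bad <- ev; bad$condition[1] <- "smell"
  expect_error(validateEvents(bad, d), "unknown condition")
  bad <- ev; bad$onset[2] <- bad$onset[1] + 1
  expect_error(validateEvents(bad[order(bad$run, bad$onset), ], d),
               "overlapping")
})

test_that("event tables round-trip through BIDS-style TSV", {
  d <- tinyDesign()
  ev <- buildEventTable(d, seed = 2)
  path <- tempfile(fileext = ".tsv")
  writeEvents(ev, path)
  back <- readEvents(path)
  expect_equal(back$onset, ev$onset)
  expect_equal(back$condition, ev$condition)
  expect_equal(back$category, ev$category)
  expect_equal(back$trial_index, ev$trial_index)
})

test_that("designs round-trip through the structured config", {
  d <- ExperimentDesign()
  cfg <- designToConfig(d)
  expect_equal(cfg$trials_per_condition, 80L)
  d2 <- designFromConfig(cfg)
  expect_equal(d2, d)
  skip_if_not_installed("jsonlite")
  path <- tempfile(fileext = ".json")
  designToConfig(d, path)
  expect_equal(designFromConfig(path), d)
})
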