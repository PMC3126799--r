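test_that("stimulus function marks acquisition instants inside the window", {
  d <- ExperimentDesign()
  # no trials -> all zero
  empty <- oneTrialEvents()[0, ]
  expect_equal(stimulusFunction(empty, d), rep(0, 1600))
  # one 10-s trial at run start: window [1, 4.6) covers samples at 2 and 4 s
  stim <- stimulusFunction(oneTrialEvents(), d)
  expect_equal(which(stim == 1), c(2L, 3L))
  # a full 80-trial condition contributes exactly 160 marked samples
  ev <- buildEventTable(d, seed = 5)
  part <- partitionByCondition(ev, d)
  stim <- stimulusFunction(ev, d)
  for (cc in conditionNames(d))
    expect_equal(sum(stim[conditionRows(part, cc)]), 160)
})

test_that("labeled stimulus function carries category signs", {
  d <- ExperimentDesign()
  ev2 <- rbind(oneTrialEvents(category = "old"),
               oneTrialEvents(category = "young"))
  ev2$onset <- c(0, 10); ev2$trial_index <- 1:2
  lab <- labeledStimulusFunction(ev2, d)
  expect_equal(which(lab == 1), c(2L, 3L))
  expect_equal(which(lab == -1), c(7L, 8L))
  # |labeled| equals the binary stimulus function for any schedule
  ev <- buildEventTable(d, seed = 9)
  expect_equal(abs(labeledStimulusFunction(ev, d)), stimulusFunction(ev, d))
  # balanced schedule sums to zero
  expect_equal(sum(labeledStimulusFunction(ev, d)), 0)
  # missing category errors
  bad <- oneTrialEvents(category = "none")
  expect_error(labeledStimulusFunction(bad, d), "category")
})

test_that("double-gamma kernel has the canonical shape", {
  k <- doubleGammaHrf(tr = 0.1)
  expect_equal(k[1], 0)
  peak <- (which.max(k) - 1) * 0.1
  expect_gte(peak, 4); expect_lte(peak, 6)
  k0 <- doubleGammaHrf(tr = 0.5, undershootRatio = 0)
  expect_true(all(k0 >= 0))
  expect_error(doubleGammaHrf(tr = 2, peakShape = -1), "positive")
  expect_error(doubleGammaHrf(tr = 0), "positive")
})

test_that("regressor convolution is causal, linear and run-confined", {
  k <- doubleGammaHrf(2)
  run <- rep(1:2, each = 20)
  expect_equal(convolveRegressor(numeric(40), k, run), numeric(40))
  # unit impulse copies the kernel, truncated at the run end
  x <- numeric(40); x[5] <- 1
  y <- convolveRegressor(x, k, run)
  expect_equal(y[5:20], k[1:16])
  expect_equal(y[21:40], numeric(20))
  # two-run convolution equals convolving each run alone
  set.seed(1)
  x <- rbinom(40, 1, 0.3)
  y2 <- convolveRegressor(x, k, run)
  y1a <- convolveRegressor(x[1:20], k, rep(1L, 20))
  y1b <- convolveRegressor(x[21:40], k, rep(1L, 20))
  expect_equal(y2, c(y1a, y1b))
  # linearity: old-only + young-only regressors add up to the combined one
  d <- ExperimentDesign()
  ev <- buildEventTable(d, seed = 2)
  evOld <- ev; evOld$category <- "old"
  evYoung <- ev; evYoung$category <- "young"
  lab <- labeledStimulusFunction(ev, d)
  labOld <- ifelse(labeledStimulusFunction(evOld, d) > 0 & lab > 0, 1, 0)
  clock <- rep(1:2, each = 800)
  hlFull <- convolveRegressor(lab, k, clock)
  hlPos <- convolveRegressor(pmax(lab, 0), k, clock)
  hlNeg <- convolveRegressor(pmin(lab, 0), k, clock)
  expect_equal(hlPos + hlNeg, hlFull, tolerance = 1e-12)
  expect_error(convolveRegressor(numeric(10), k, rep(1, 9)), "length")
})

test_that("boldRegressors assembles consistent hs/hl pairs", {
  d <- ExperimentDesign()
  ev <- buildEventTable(d, seed = 7)
  reg <- boldRegressors(ev, d)
  expect_length(simulatedBold(reg), 1600)
  expect_length(labeledBold(reg), 1600)
  # a single-category schedule makes the two regressors coincide
  evOld <- ev; evOld$category <- "old"
  regOld <- boldRegressors(evOld, d)
  expect_equal(labeledBold(regOld), simulatedBold(regOld), tolerance = 1e-12)
})
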