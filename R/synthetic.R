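#' Configure the synthetic-data generator
#'
#' Defaults describe the reference simulated subject: 6000 voxels of which 60
#' are category-informative (30 placed inside each STS/MTG Talairach cube),
#' equal category effect size in all four conditions, and within-class
#' pattern dispersion lowest for the congruent condition (0.1), intermediate
#' for incongruent (0.5) and highest for the unimodal conditions (0.6) --
#' i.e. congruent audiovisual stimulation yields the most reproducible
#' trial patterns while leaving amplitudes (hence pattern norms) untouched.
#'
#' @param nVoxels total voxels
#' @param nInformative planted informative voxels
#' @param nRoiPerSide informative voxels placed in each ROI cube
#' @param categoryAmplitude per-condition category effect size (named or
#'   scalar, signal units)
#' @param withinClassDispersion per-condition sd of the trial-level
#'   multiplicative jitter on the informative pattern
#' @param noiseSd additive measurement noise sd
#' @param activationAmplitude shared stimulus-locked response amplitude
#' @param baseline mean raw signal level
#' @param driftSd sd of per-voxel linear drift per run
#' @param seed subject seed
#' @param design design the config must match (for condition names)
#' @return a \linkS4class{SyntheticConfig}
#' @export
syntheticConfig <- function(nVoxels = 6000L, nInformative = 60L,
                            nRoiPerSide = 30L,
                            categoryAmplitude = 1.6,
                            withinClassDispersion = c(congruent = 0.1,
                                                      incongruent = 0.5,
                                                      picture = 0.6,
                                                      speech = 0.6),
                            noiseSd = 1, activationAmplitude = 2,
                            baseline = 100, driftSd = 1, seed = 1L,
                            design = ExperimentDesign()) {
  expand <- function(v) {
    if (length(v) == 1L && is.null(names(v)))
      v <- setNames(rep(v, length(design@conditions)), design@conditions)
    if (!all(design@conditions %in% names(v)))
      stop("per-condition parameter must name every condition")
    v[design@conditions]
  }
  new("SyntheticConfig",
      nVoxels = as.integer(nVoxels), nInformative = as.integer(nInformative),
      nRoiPerSide = as.integer(nRoiPerSide),
      categoryAmplitude = expand(categoryAmplitude),
      withinClassDispersion = expand(withinClassDispersion),
      noiseSd = as.numeric(noiseSd),
      activationAmplitude = as.numeric(activationAmplitude),
      baseline = as.numeric(baseline), driftSd = as.numeric(driftSd),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nVoxels, "voxels,",
      object@nInformative, "informative (", 2 * object@nRoiPerSide,
      "in ROI cubes)\n")
  cat("  category amplitude:",
      paste(sprintf("%s=%g", names(object@categoryAmplitude),
                    object@categoryAmplitude), collapse = ", "), "\n")
  cat("  within-class dispersion:",
      paste(sprintf("%s=%g", names(object@withinClassDispersion),
                    object@withinClassDispersion), collapse = ", "), "\n")
  cat("  noise sd:", object@noiseSd, " activation:",
      object@activationAmplitude, " seed:", object@seed, "\n")
})

# coordinates: nRoiPerSide informative voxels per ROI cube, everything else
# scattered in a brain-sized box with both cubes carved out
sampleCoords <- function(nVoxels, informative, nRoiPerSide, specs) {
  coords <- matrix(NA_real_, nVoxels, 3)
  cubeUniform <- function(spec, n) {
    lo <- spec@center - spec@halfWidth
    hi <- spec@center + spec@halfWidth
    cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
          runif(n, lo[3], hi[3]))
  }
  roiVox <- informative[seq_len(2 * nRoiPerSide)]
  coords[roiVox[seq_len(nRoiPerSide)], ] <- cubeUniform(specs[[1]], nRoiPerSide)
  coords[roiVox[nRoiPerSide + seq_len(nRoiPerSide)], ] <-
    cubeUniform(specs[[2]], nRoiPerSide)
  rest <- which(is.na(coords[, 1]))
  need <- length(rest)
  got <- 0L
  out <- matrix(0, need, 3)
  while (got < need) {
    k <- 2L * (need - got) + 16L
    cand <- cbind(runif(k, -75, 75), runif(k, -110, 80), runif(k, -55, 85))
    keep <- !(inRoiCube(cand, specs[[1]]) | inRoiCube(cand, specs[[2]]))
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), need - got)
    if (take > 0) out[got + seq_len(take), ] <- cand[seq_len(take), , drop = FALSE]
    got <- got + take
  }
  coords[rest, ] <- out
  coords
}

#' Simulate one subject of the audiovisual experiment
#'
#' Generates a raw samples x voxels matrix with the structure the analysis
#' assumes. Every voxel carries a stimulus-locked activation response with a
#' fixed per-voxel loading; informative voxels additionally carry a
#' category-signed effect whose trial-to-trial amplitude is jittered
#' multiplicatively with a condition-dependent dispersion, so the congruent
#' condition (smallest dispersion) produces the most reproducible within-
#' class pattern directions at unchanged expected amplitude. Evoked
#' responses are the within-trial convolution of the trial's stimulus
#' function with the double-gamma HRF (no carry-over between trials, so
#' noise-free patterns within a condition and category are exactly equal).
#' Baseline, per-run linear drift and i.i.d. Gaussian noise are added on top.
#'
#' Informative voxels receive activation loadings drawn from the top of the
#' loading range (category-selective cortex in this paradigm is strongly
#' stimulus-driven), so correlation screening retains them.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param design an \linkS4class{ExperimentDesign}
#' @return an \linkS4class{FmriExperiment} with ground truth in
#'   \code{rowData} and the schedule in \code{metadata}
#' @export
generateSubject <- function(config = syntheticConfig(),
                            design = ExperimentDesign()) {
  events <- buildEventTable(design, seed = deriveSeed(config@seed, 1L))
  nv <- config@nVoxels
  withSeed(deriveSeed(config@seed, 2L), {
    informative <- sort(sample.int(nv, config@nInformative))
    signs <- numeric(nv)
    signs[informative] <- sample(rep(c(1, -1),
                                     length.out = config@nInformative))
    aLoad <- runif(nv, 0.2, 1.0)
    aLoad[informative] <- runif(config@nInformative, 2.2, 2.8)
    sLoad <- runif(nv, 0.7, 1.3)
    coords <- sampleCoords(nv, informative, config@nRoiPerSide, stsMtgRois())

    # within-trial evoked response profile (one value per trial sample)
    spt <- samplesPerTrial(design)
    tt <- seq(0, by = design@tr, length.out = spt)
    w0 <- min(design@repetitionOnsets)
    w1 <- max(design@repetitionOnsets) + design@stimulusDuration
    stimLocal <- as.numeric(tt >= w0 - 1e-9 & tt < w1 - 1e-9)
    kernel <- doubleGammaHrf(design@tr)
    rho <- convolveRegressor(stimLocal, kernel, rep(1L, spt))

    # per-trial amplitude of every voxel
    ev <- events[order(events$trial_index), ]
    nTrial <- nrow(ev)
    eps <- rnorm(nTrial) * config@withinClassDispersion[ev$condition]
    beta <- config@categoryAmplitude[ev$condition]
    catSign <- ifelse(ev$category == design@categories[1], 1, -1)
    amp <- matrix(config@activationAmplitude, nTrial, 1) %*% t(aLoad)
    inf <- informative
    amp[, inf] <- amp[, inf] +
      (catSign * beta * (1 + eps)) %*% t(signs[inf] * sLoad[inf])

    # lay trials out in time order and scale by the evoked profile
    ord <- order(ev$run, ev$onset)
    values <- amp[rep(ord, each = spt), , drop = FALSE] * rep(rho, nTrial)

    # baseline, drift, noise
    spr <- samplesPerRun(design)
    drift <- rnorm(nv, sd = config@driftSd)
    ramp <- rep(seq(-0.5, 0.5, length.out = spr), design@runs)
    values <- values + config@baseline + outer(ramp, drift) +
      matrix(rnorm(length(values), sd = config@noiseSd), nrow(values))

    FmriExperiment(values, events, design, coords = coords,
                   informative = seq_len(nv) %in% informative,
                   categorySign = signs)
  })
}

#' Simulate an independent cohort of subjects
#'
#' Subject seeds are derived deterministically from the cohort seed, so the
#' same (config, nSubjects) always yields the identical cohort while
#' subjects differ from each other.
#'
#' @param config a \linkS4class{SyntheticConfig}; its seed is the cohort seed
#' @param nSubjects number of subjects
#' @param design an \linkS4class{ExperimentDesign}
#' @return list of \linkS4class{FmriExperiment}
#' @export
generateCohort <- function(config = syntheticConfig(), nSubjects = 9L,
                           design = ExperimentDesign()) {
  stopifnot(nSubjects >= 1)
  lapply(seq_len(nSubjects), function(i) {
    cfg <- config
    cfg@seed <- as.integer(deriveSeed(config@seed, i, stage = 7L))
    generateSubject(cfg, design)
  })
}
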