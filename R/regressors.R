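#' Canonical double-gamma hemodynamic response function
#'
#' The kernel is the difference of two gamma densities: a response peak
#' (default shape 6, scale 1 s, peaking at 5 s) minus a scaled undershoot
#' (default shape 16, scale 1 s, ratio 1/6), sampled on the acquisition grid
#' and normalized to unit peak.
#'
#' @param tr sampling interval, seconds
#' @param lengthOut kernel support, seconds (>= 24 recommended)
#' @param peakShape,peakScale gamma parameters of the response peak
#' @param undershootShape,undershootScale gamma parameters of the undershoot
#' @param undershootRatio weight of the undershoot relative to the peak;
#'   0 gives a single (everywhere nonnegative) gamma density
#' @param normalize divide by the maximum so the kernel peaks at 1
#' @return numeric kernel sampled at \code{seq(0, lengthOut, by = tr)}
#' @examples
#' k <- doubleGammaHrf(tr = 0.1)
#' (which.max(k) - 1) * 0.1   # peak close to 5 s
#' @export
doubleGammaHrf <- function(tr, lengthOut = 32,
                           peakShape = 6, peakScale = 1,
                           undershootShape = 16, undershootScale = 1,
                           undershootRatio = 1 / 6, normalize = TRUE) {
  if (tr <= 0) stop("tr must be positive")
  if (peakShape <= 0 || peakScale <= 0 || undershootShape <= 0 ||
      undershootScale <= 0)
    stop("gamma shape and scale parameters must be positive")
  if (undershootRatio < 0) stop("undershootRatio must be >= 0")
  tt <- seq(0, lengthOut, by = tr)
  k <- stats::dgamma(tt, shape = peakShape, scale = peakScale) -
    undershootRatio * stats::dgamma(tt, shape = undershootShape,
                                    scale = undershootScale)
  if (normalize) k <- k / max(k)
  k
}

# acquisition time of every sample, and its run, for a design
sampleClock <- function(design) {
  spr <- samplesPerRun(design)
  list(time = rep(seq(0, by = design@tr, length.out = spr), design@runs),
       run = rep(seq_len(design@runs), each = spr))
}

# map each sample to the trial covering it (by run and onset), NA outside
sampleTrialMap <- function(events, design) {
  clock <- sampleClock(design)
  idx <- rep(NA_integer_, length(clock$time))
  for (i in seq_len(nrow(events))) {
    r <- events$run[i]
    from <- events$onset[i]
    sel <- which(clock$run == r & clock$time >= from - 1e-9 &
                   clock$time < from + events$duration[i] - 1e-9)
    idx[sel] <- i
  }
  idx
}

#' Stimulus functions on the acquisition grid
#'
#' \code{stimulusFunction} returns the binary stimulus function: 1 at samples
#' acquired during a trial's stimulation window, 0 elsewhere. The stimulation
#' window of a trial is \code{[onset + first repetition onset, onset + last
#' repetition onset + stimulus duration)}. \code{labeledStimulusFunction}
#' returns the category-signed version: +1 for the first design category
#' ("old"), -1 for the second ("young"), 0 without stimulation; for
#' incongruent audiovisual trials the sign follows the category recorded in
#' the event table (the category of the face picture).
#'
#' @param events event table (see \code{\link{buildEventTable}})
#' @param design an \linkS4class{ExperimentDesign}
#' @return numeric vector of length \code{totalSamples(design)}
#' @export
stimulusFunction <- function(events, design) {
  validateEvents(events, design)
  clock <- sampleClock(design)
  stim <- numeric(length(clock$time))
  w0 <- min(design@repetitionOnsets)
  w1 <- max(design@repetitionOnsets) + design@stimulusDuration
  for (i in seq_len(nrow(events))) {
    sel <- clock$run == events$run[i] &
      clock$time >= events$onset[i] + w0 - 1e-9 &
      clock$time < events$onset[i] + w1 - 1e-9
    stim[sel] <- 1
  }
  stim
}

#' @rdname stimulusFunction
#' @export
labeledStimulusFunction <- function(events, design) {
  stim <- stimulusFunction(events, design)
  clock <- sampleClock(design)
  trialOf <- sampleTrialMap(events, design)
  on <- which(stim != 0)
  cats <- events$category[trialOf[on]]
  if (any(is.na(cats)) || any(cats == "none"))
    stop("every stimulated trial must carry a semantic category")
  sign <- ifelse(cats == design@categories[1], 1, -1)
  out <- numeric(length(stim))
  out[on] <- sign
  out
}

#' Causal convolution of a stimulus function with an HRF kernel
#'
#' Convolves per run (no bleed across run boundaries) and truncates at the
#' run end, so the output has the input's length.
#'
#' @param stim stimulus function, one value per sample
#' @param kernel HRF kernel (see \code{\link{doubleGammaHrf}})
#' @param run run identifier per sample; must be contiguous blocks
#' @return numeric vector, same length as \code{stim}
#' @export
convolveRegressor <- function(stim, kernel, run) {
  if (length(stim) != length(run))
    stop("stim and run must have the same length")
  if (!all(is.finite(stim)) || !all(is.finite(kernel)))
    stop("inputs must be finite")
  if (any(run != cummax(run))) stop("run blocks must be contiguous")
  out <- numeric(length(stim))
  for (r in unique(run)) {
    sel <- which(run == r)
    x <- stim[sel]
    y <- numeric(length(x))
    for (l in seq_along(kernel)) {
      if (kernel[l] == 0) next
      if (l == 1L) y <- y + kernel[l] * x
      else {
        n <- length(x) - (l - 1L)
        if (n <= 0) break
        y[l:length(x)] <- y[l:length(x)] + kernel[l] * x[1:n]
      }
    }
    out[sel] <- y
  }
  out
}

#' Build the simulated and labeled BOLD regressors for a schedule
#'
#' Convolves the binary and the category-signed stimulus functions with the
#' same double-gamma kernel, per run.
#'
#' @param events event table
#' @param design an \linkS4class{ExperimentDesign}
#' @param kernel HRF kernel; default \code{doubleGammaHrf(design@tr)}
#' @return a \linkS4class{BoldRegressors}
#' @export
boldRegressors <- function(events, design, kernel = NULL) {
  if (is.null(kernel)) kernel <- doubleGammaHrf(design@tr)
  clock <- sampleClock(design)
  hs <- convolveRegressor(stimulusFunction(events, design), kernel, clock$run)
  hl <- convolveRegressor(labeledStimulusFunction(events, design), kernel,
                          clock$run)
  new("BoldRegressors", hs = hs, hl = hl,
      sampleTimes = clock$time, run = as.integer(clock$run))
}

#' @describeIn boldRegressors the simulated (activation) BOLD regressor
#' @param x a BoldRegressors object
#' @export
setMethod("simulatedBold", "BoldRegressors", function(x) x@hs)

#' @describeIn boldRegressors the labeled (category-signed) BOLD regressor
#' @export
setMethod("labeledBold", "BoldRegressors", function(x) x@hl)

#' @describeIn boldRegressors run id per sample
#' @export
setMethod("runIds", "BoldRegressors", function(x) x@run)

setMethod("show", "BoldRegressors", function(object) {
  cat("BoldRegressors:", length(object@hs), "samples,",
      length(unique(object@run)), "runs\n")
  cat("  |hs| range:", paste(signif(range(object@hs), 3), collapse = " .. "),
      "; hl range:", paste(signif(range(object@hl), 3), collapse = " .. "),
      "\n")
})
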