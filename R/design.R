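#' Construct an experimental design
#'
#' The default values reproduce the reference four-condition audiovisual
#' design: 80 trials per condition (320 in total), 10-s trials acquired at
#' TR = 2 s (5 samples per trial, 1600 samples overall), four stimulus
#' repetitions at 1--4 s into each trial lasting 0.6 s each, two runs of two
#' conditions, and the two semantic categories balanced 40/40 within every
#' condition.
#'
#' @param conditions condition labels, in order
#' @param trialsPerCondition trials per condition
#' @param trialDuration trial length, seconds
#' @param tr repetition time, seconds
#' @param repetitionOnsets within-trial stimulus onsets, seconds
#' @param stimulusDuration stimulus duration per repetition, seconds
#' @param runs number of runs
#' @param conditionsPerRun conditions per run
#' @param categories the two semantic category labels
#' @return an \linkS4class{ExperimentDesign}
#' @examples
#' d <- ExperimentDesign()
#' totalSamples(d)   # 1600
#' @export
ExperimentDesign <- function(conditions = c("congruent", "incongruent",
                                            "picture", "speech"),
                             trialsPerCondition = 80L,
                             trialDuration = 10,
                             tr = 2,
                             repetitionOnsets = c(1, 2, 3, 4),
                             stimulusDuration = 0.6,
                             runs = 2L,
                             conditionsPerRun = 2L,
                             categories = c("old", "young")) {
  new("ExperimentDesign",
      conditions = as.character(conditions),
      trialsPerCondition = as.integer(trialsPerCondition),
      trialDuration = as.numeric(trialDuration),
      tr = as.numeric(tr),
      repetitionOnsets = as.numeric(sort(repetitionOnsets)),
      stimulusDuration = as.numeric(stimulusDuration),
      runs = as.integer(runs),
      conditionsPerRun = as.integer(conditionsPerRun),
      categories = as.character(categories))
}

#' @describeIn ExperimentDesign condition labels
#' @param x an ExperimentDesign
#' @export
setMethod("conditionNames", "ExperimentDesign", function(x) x@conditions)

#' @describeIn ExperimentDesign category labels
#' @export
setMethod("categoryNames", "ExperimentDesign", function(x) x@categories)

#' @describeIn ExperimentDesign acquired samples per trial
#' @export
setMethod("samplesPerTrial", "ExperimentDesign",
          function(x) as.integer(round(x@trialDuration / x@tr)))

#' @describeIn ExperimentDesign total acquired samples across all runs
#' @export
setMethod("totalSamples", "ExperimentDesign", function(x)
  samplesPerTrial(x) * x@trialsPerCondition * length(x@conditions))

trialsPerRun <- function(design)
  design@trialsPerCondition * design@conditionsPerRun

samplesPerRun <- function(design)
  trialsPerRun(design) * samplesPerTrial(design)

setMethod("show", "ExperimentDesign", function(object) {
  cat("ExperimentDesign:", length(object@conditions), "conditions x",
      object@trialsPerCondition, "trials,", object@runs, "runs\n")
  cat("  conditions:", paste(object@conditions, collapse = ", "), "\n")
  cat("  categories:", paste(object@categories, collapse = ", "),
      "(balanced)\n")
  cat("  trial:", object@trialDuration, "s, TR", object@tr,
      "s; stimulus onsets at",
      paste(object@repetitionOnsets, collapse = ", "), "s\n")
  cat("  total samples:", totalSamples(object), "\n")
})

# run a block of code under a temporary RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# deterministic derivation of child seeds, kept below 2^31
deriveSeed <- function(seed, index, stage = 0L) {
  (as.double(seed) * 48271 + as.double(index) * 16807 +
     as.double(stage) * 69621) %% 2147483563
}

#' Build a randomized trial schedule for a design
#'
#' Assigns conditions to runs in pairs (first two conditions to run 1, last
#' two to run 2 by default), interleaves the two conditions of each run in
#' random order, and randomizes the category sequence of each condition under
#' the constraint that every contiguous block of
#' \code{trialsPerCondition / 4} trials is category-balanced, so each
#' cross-validation fold holds equally many trials of both categories.
#'
#' @param design an \linkS4class{ExperimentDesign}
#' @param seed integer seed for the schedule randomization
#' @return a data.frame (event table) with columns \code{run}, \code{onset},
#'   \code{duration}, \code{condition}, \code{category}, \code{trial_index};
#'   onsets are 0-based seconds from run start
#' @export
buildEventTable <- function(design, seed = 1L) {
  withSeed(seed, {
    nf <- 4L
    perFold <- design@trialsPerCondition / nf
    perCat <- perFold / length(design@categories)
    runCond <- split(design@conditions,
                     rep(seq_len(design@runs), each = design@conditionsPerRun))
    out <- vector("list", design@runs)
    trial0 <- 0L
    for (r in seq_len(design@runs)) {
      conds <- runCond[[r]]
      # interleave the run's conditions in random order
      condSeq <- sample(rep(conds, each = design@trialsPerCondition))
      # fold-balanced category sequence per condition
      catSeq <- lapply(conds, function(cc) {
        unlist(lapply(seq_len(nf), function(i)
          sample(rep(design@categories, each = perCat))))
      })
      names(catSeq) <- conds
      taken <- setNames(rep(0L, length(conds)), conds)
      cats <- character(length(condSeq))
      for (i in seq_along(condSeq)) {
        cc <- condSeq[i]
        taken[cc] <- taken[cc] + 1L
        cats[i] <- catSeq[[cc]][taken[cc]]
      }
      out[[r]] <- data.frame(
        run = r,
        onset = (seq_along(condSeq) - 1) * design@trialDuration,
        duration = design@trialDuration,
        condition = condSeq,
        category = cats,
        trial_index = trial0 + seq_along(condSeq),
        stringsAsFactors = FALSE)
      trial0 <- trial0 + length(condSeq)
    }
    do.call(rbind, out)
  })
}

#' Validate an event table against a design
#'
#' Checks that onsets are strictly increasing and trials non-overlapping
#' within each run, and that all condition and category labels are known.
#'
#' @param events event table as returned by \code{\link{buildEventTable}}
#' @param design the \linkS4class{ExperimentDesign}
#' @return the event table, invisibly
#' @export
validateEvents <- function(events, design) {
  need <- c("run", "onset", "duration", "condition", "category", "trial_index")
  if (!all(need %in% colnames(events)))
    stop("event table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(events$condition), design@conditions)
  if (length(bad))
    stop("unknown condition(s) in event table: ", paste(bad, collapse = ", "))
  badc <- setdiff(unique(events$category), c(design@categories, "none", NA))
  if (length(badc))
    stop("unknown category label(s): ", paste(badc, collapse = ", "))
  for (r in unique(events$run)) {
    e <- events[events$run == r, , drop = FALSE]
    e <- e[order(e$onset), , drop = FALSE]
    if (any(diff(e$onset) <= 0))
      stop("onsets must be strictly increasing within run ", r)
    if (any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)] - 1e-9))
      stop("overlapping trials in run ", r)
  }
  invisible(events)
}

#' Read or write an event table (BIDS-style tab-separated values)
#'
#' @param path file path
#' @return \code{readEvents}: the event table data.frame
#' @export
readEvents <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  ev
}

#' @rdname readEvents
#' @param events event table data.frame
#' @export
writeEvents <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a design as a structured configuration
#'
#' \code{designToConfig} returns (and optionally writes as JSON) a plain list
#' whose keys mirror the \linkS4class{ExperimentDesign} fields;
#' \code{designFromConfig} rebuilds the design from such a list or JSON file.
#'
#' @param design an \linkS4class{ExperimentDesign}
#' @param path optional JSON output path (requires the jsonlite package)
#' @return \code{designToConfig}: the configuration list, invisibly when
#'   written to a file; \code{designFromConfig}: an ExperimentDesign
#' @export
designToConfig <- function(design, path = NULL) {
  cfg <- list(conditions = design@conditions,
              trials_per_condition = design@trialsPerCondition,
              trial_duration_s = design@trialDuration,
              tr_s = design@tr,
              repetition_onsets_s = design@repetitionOnsets,
              stimulus_duration_s = design@stimulusDuration,
              runs = design@runs,
              conditions_per_run = design@conditionsPerRun,
              categories = design@categories)
  if (!is.null(path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing a design config requires the jsonlite package")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    return(invisible(cfg))
  }
  cfg
}

#' @rdname designToConfig
#' @param x a configuration list, or the path of a JSON file written by
#'   \code{designToConfig}
#' @export
designFromConfig <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading a design config requires the jsonlite package")
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  ExperimentDesign(conditions = x$conditions,
                   trialsPerCondition = x$trials_per_condition,
                   trialDuration = x$trial_duration_s,
                   tr = x$tr_s,
                   repetitionOnsets = x$repetition_onsets_s,
                   stimulusDuration = x$stimulus_duration_s,
                   runs = x$runs,
                   conditionsPerRun = x$conditions_per_run,
                   categories = x$categories)
}
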