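#' Partition the data rows by stimulus condition, with trial-aligned folds
#'
#' Splits the sample rows into one segment per condition (in time order; 400
#' rows per condition in the reference design) and assigns each trial of a
#' condition to one of \code{nFolds} contiguous, trial-aligned
#' cross-validation folds (20 trials, 100 rows per fold in the reference
#' design).
#'
#' @param events event table
#' @param design the \linkS4class{ExperimentDesign}
#' @param nFolds number of folds
#' @return a \linkS4class{ConditionPartition}
#' @export
partitionByCondition <- function(events, design, nFolds = 4L) {
  validateEvents(events, design)
  spt <- samplesPerTrial(design)
  spr <- samplesPerRun(design)
  rows <- list(); trials <- list()
  for (cc in design@conditions) {
    e <- events[events$condition == cc, , drop = FALSE]
    e <- e[order(e$run, e$onset), , drop = FALSE]
    if (nrow(e) != design@trialsPerCondition)
      stop("condition ", cc, " has ", nrow(e), " trials; design expects ",
           design@trialsPerCondition)
    if (nrow(e) %% nFolds != 0)
      stop("trials per condition must divide evenly into folds")
    startRow <- (e$run - 1L) * spr + as.integer(round(e$onset / design@tr)) + 1L
    fold <- rep(seq_len(nFolds), each = nrow(e) / nFolds)
    trials[[cc]] <- data.frame(trial_index = e$trial_index,
                               category = e$category,
                               start_row = startRow, fold = fold,
                               stringsAsFactors = FALSE)
    rows[[cc]] <- as.integer(outer(0:(spt - 1L), startRow, "+"))
  }
  new("ConditionPartition", conditions = design@conditions,
      rows = rows, trials = trials, nFolds = as.integer(nFolds))
}

#' @describeIn partitionByCondition all data rows of one condition, time order
#' @param x a ConditionPartition
#' @param condition condition label
#' @export
setMethod("conditionRows", "ConditionPartition", function(x, condition) {
  if (!condition %in% x@conditions) stop("unknown condition: ", condition)
  x@rows[[condition]]
})

#' @describeIn partitionByCondition per-trial table (trial_index, category,
#'   start_row, fold) of one condition
#' @export
setMethod("trialInfo", "ConditionPartition", function(x, condition) {
  if (!condition %in% x@conditions) stop("unknown condition: ", condition)
  x@trials[[condition]]
})

#' @describeIn partitionByCondition data rows of one condition belonging to
#'   the test fold ("test") or to the remaining training folds ("train")
#' @param fold fold number in 1..nFolds
#' @param which "test" or "train"
#' @export
setMethod("foldRows", "ConditionPartition",
          function(x, condition, fold, which = c("test", "train")) {
  which <- match.arg(which)
  ti <- trialInfo(x, condition)
  if (!fold %in% seq_len(x@nFolds)) stop("fold must be in 1..", x@nFolds)
  keep <- if (which == "test") ti$fold == fold else ti$fold != fold
  spt <- length(x@rows[[condition]]) / nrow(ti)
  as.integer(outer(0:(spt - 1L), ti$start_row[keep], "+"))
})

setMethod("conditionNames", "ConditionPartition", function(x) x@conditions)

setMethod("show", "ConditionPartition", function(object) {
  cat("ConditionPartition:", length(object@conditions), "conditions,",
      object@nFolds, "trial-aligned folds\n")
  for (cc in object@conditions)
    cat("  ", cc, ": ", length(object@rows[[cc]]), " rows / ",
        nrow(object@trials[[cc]]), " trials\n", sep = "")
})
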