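#' Construct an FmriExperiment from a time x voxel matrix
#'
#' @param bold numeric matrix, samples (rows, time order) x voxels (columns)
#' @param events event table describing the trials
#' @param design the \linkS4class{ExperimentDesign}
#' @param coords optional voxels x 3 matrix of Talairach (x, y, z), mm
#' @param informative optional logical per voxel: planted ground truth
#' @param categorySign optional numeric per voxel in \{-1, 0, +1\}: sign of
#'   the planted category preference (+1 = first category)
#' @return an \linkS4class{FmriExperiment}
#' @export
FmriExperiment <- function(bold, events, design, coords = NULL,
                           informative = NULL, categorySign = NULL) {
  validateEvents(events, design)
  if (nrow(bold) != totalSamples(design))
    stop("bold has ", nrow(bold), " rows; design expects ",
         totalSamples(design))
  clock <- sampleClock(design)
  trialOf <- sampleTrialMap(events, design)
  cd <- S4Vectors::DataFrame(
    run = as.integer(clock$run),
    sample_time = clock$time,
    trial_index = events$trial_index[trialOf],
    condition = events$condition[trialOf],
    category = events$category[trialOf])
  nv <- ncol(bold)
  rd <- S4Vectors::DataFrame(voxel = seq_len(nv))
  if (!is.null(coords)) {
    stopifnot(nrow(coords) == nv, ncol(coords) == 3L)
    rd$x <- coords[, 1]; rd$y <- coords[, 2]; rd$z <- coords[, 3]
  }
  if (!is.null(informative)) rd$informative <- as.logical(informative)
  if (!is.null(categorySign)) rd$category_sign <- as.numeric(categorySign)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bold = t(bold)), rowData = rd, colData = cd,
    metadata = list(design = design, events = events))
  new("FmriExperiment", se)
}

#' @describeIn FmriExperiment the samples x voxels data matrix
#' @param x an FmriExperiment
#' @export
setMethod("boldMatrix", "FmriExperiment", function(x)
  t(SummarizedExperiment::assay(x, "bold")))

#' @describeIn FmriExperiment the event table
#' @export
setMethod("eventTable", "FmriExperiment", function(x)
  S4Vectors::metadata(x)$events)

#' @describeIn FmriExperiment the design
#' @export
setMethod("experimentDesign", "FmriExperiment", function(x)
  S4Vectors::metadata(x)$design)

#' @describeIn FmriExperiment run id per sample
#' @export
setMethod("runIds", "FmriExperiment", function(x)
  SummarizedExperiment::colData(x)$run)

#' @describeIn FmriExperiment voxels x 3 Talairach coordinate matrix
#' @export
setMethod("voxelCoords", "FmriExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!all(c("x", "y", "z") %in% colnames(rd)))
    stop("no voxel coordinates available")
  as.matrix(rd[, c("x", "y", "z")])
})

#' @describeIn FmriExperiment indices of planted informative voxels
#'   (synthetic data only)
#' @export
setMethod("informativeVoxels", "FmriExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"informative" %in% colnames(rd))
    stop("no ground truth available for this dataset")
  which(rd$informative)
})

setMethod("show", "FmriExperiment", function(object) {
  d <- S4Vectors::metadata(object)$design
  cat("FmriExperiment:", ncol(object), "samples x", nrow(object), "voxels\n")
  if (!is.null(d))
    cat("  design:", length(d@conditions), "conditions,",
        d@trialsPerCondition, "trials each, TR", d@tr, "s\n")
  rd <- SummarizedExperiment::rowData(object)
  if ("informative" %in% colnames(rd))
    cat("  planted informative voxels:", sum(rd$informative), "\n")
})

# replace the data matrix, keeping all metadata
setBoldMatrix <- function(x, values) {
  SummarizedExperiment::assay(x, "bold") <- t(values)
  x
}
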