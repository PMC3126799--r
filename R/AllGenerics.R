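#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @export
setGeneric("categoryNames", function(x) standardGeneric("categoryNames"))

#' @export
setGeneric("samplesPerTrial", function(x) standardGeneric("samplesPerTrial"))

#' @export
setGeneric("totalSamples", function(x) standardGeneric("totalSamples"))

#' @export
setGeneric("boldMatrix", function(x) standardGeneric("boldMatrix"))

#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @export
setGeneric("runIds", function(x) standardGeneric("runIds"))

#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))

#' @export
setGeneric("informativeVoxels", function(x) standardGeneric("informativeVoxels"))

#' @export
setGeneric("experimentDesign", function(x) standardGeneric("experimentDesign"))

#' @export
setGeneric("simulatedBold", function(x) standardGeneric("simulatedBold"))

#' @export
setGeneric("labeledBold", function(x) standardGeneric("labeledBold"))

#' @export
setGeneric("conditionRows", function(x, condition) standardGeneric("conditionRows"))

#' @export
setGeneric("trialInfo", function(x, condition) standardGeneric("trialInfo"))

#' @export
setGeneric("foldRows",
           function(x, condition, fold, which = c("test", "train"))
             standardGeneric("foldRows"))

#' @export
setGeneric("activatedVoxels", function(x) standardGeneric("activatedVoxels"))

#' @export
setGeneric("selectedVoxels", function(x) standardGeneric("selectedVoxels"))

#' @export
setGeneric("patternMatrix", function(x) standardGeneric("patternMatrix"))

#' @export
setGeneric("reproducibilityIndex",
           function(x, ...) standardGeneric("reproducibilityIndex"))

#' @export
setGeneric("averageNorm", function(x, ...) standardGeneric("averageNorm"))

#' @export
setGeneric("applyMask", function(x, mask) standardGeneric("applyMask"))

#' @export
setGeneric("zscoreRuns", function(x) standardGeneric("zscoreRuns"))

#' @export
setGeneric("detrendRuns", function(x) standardGeneric("detrendRuns"))
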