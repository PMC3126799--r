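#' @import methods
#' @importFrom stats cor rnorm runif sd pt qnorm pnorm p.adjust t.test aov
#' @importFrom stats setNames predict dgamma
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

#' Experimental design of the four-condition audiovisual experiment
#'
#' Describes the trial/condition/timing structure of an event-related fMRI
#' experiment with four stimulus conditions (congruent audiovisual,
#' incongruent audiovisual, unimodal picture, unimodal speech) and two
#' balanced semantic categories ("old" vs "young" faces/words). Every trial
#' lasts \code{trialDuration} seconds and presents \code{length(repetitionOnsets)}
#' repetitions of the stimulus; volumes are acquired every \code{tr} seconds.
#'
#' @slot conditions ordered condition labels (one per experimental condition)
#' @slot trialsPerCondition number of trials per condition
#' @slot trialDuration trial length in seconds (must be a multiple of \code{tr})
#' @slot tr repetition time of the acquisition, seconds
#' @slot repetitionOnsets within-trial stimulus onsets, seconds from trial start
#' @slot stimulusDuration duration of each stimulus repetition, seconds
#' @slot runs number of scanning runs
#' @slot conditionsPerRun number of conditions assigned to each run
#' @slot categories the two semantic category labels
#'
#' @name ExperimentDesign-class
#' @aliases ExperimentDesign-class
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(
    conditions = "character",
    trialsPerCondition = "integer",
    trialDuration = "numeric",
    tr = "numeric",
    repetitionOnsets = "numeric",
    stimulusDuration = "numeric",
    runs = "integer",
    conditionsPerRun = "integer",
    categories = "character"
  )
)

setValidity("ExperimentDesign", function(object) {
  msg <- NULL
  if (anyDuplicated(object@conditions))
    msg <- c(msg, "condition labels must be unique")
  if (length(object@conditions) != object@runs * object@conditionsPerRun)
    msg <- c(msg, "length(conditions) must equal runs * conditionsPerRun")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (abs(object@trialDuration %% object@tr) > 1e-9)
    msg <- c(msg, "trialDuration must be divisible by tr")
  if (length(object@categories) != 2L)
    msg <- c(msg, "exactly two semantic categories are supported")
  nf <- 4L * length(object@categories)
  if (object@trialsPerCondition %% nf != 0L)
    msg <- c(msg, sprintf(
      "trialsPerCondition must be a multiple of %d (4 folds x balanced categories)", nf))
  if (any(object@repetitionOnsets < 0) ||
      max(object@repetitionOnsets) + object@stimulusDuration > object@trialDuration)
    msg <- c(msg, "stimulation window must lie inside the trial")
  if (is.null(msg)) TRUE else msg
})

#' BOLD regressors derived from the stimulus schedule
#'
#' Holds the simulated BOLD response (convolution of the binary stimulus
#' function with the hemodynamic response function) and the labeled BOLD
#' response (convolution of the category-signed stimulus function with the
#' same kernel), together with the acquisition time and run of each sample.
#'
#' @slot hs simulated BOLD response, one value per acquired sample
#' @slot hl labeled (category-signed) BOLD response, same length
#' @slot sampleTimes acquisition time of each sample, seconds from run start
#' @slot run run identifier of each sample
#'
#' @name BoldRegressors-class
#' @exportClass BoldRegressors
setClass("BoldRegressors",
  representation(hs = "numeric", hl = "numeric",
                 sampleTimes = "numeric", run = "integer")
)

setValidity("BoldRegressors", function(object) {
  n <- length(object@hs)
  if (length(object@hl) != n || length(object@sampleTimes) != n ||
      length(object@run) != n)
    return("hs, hl, sampleTimes and run must have equal length")
  TRUE
})

#' Condition-wise partition of the data matrix with trial-aligned folds
#'
#' Maps each condition to its rows of the (time x voxel) data matrix and to a
#' trial-aligned k-fold split used for cross-validated voxel selection,
#' pattern extraction and decoding. Folds are contiguous blocks of trials;
#' every sample of a trial shares the trial's fold.
#'
#' @slot conditions condition labels, in design order
#' @slot rows named list: condition -> integer row indices (global, time order)
#' @slot trials named list: condition -> data.frame with columns
#'   \code{trial_index}, \code{category}, \code{start_row}, \code{fold}
#' @slot nFolds number of cross-validation folds
#'
#' @name ConditionPartition-class
#' @exportClass ConditionPartition
setClass("ConditionPartition",
  representation(conditions = "character", rows = "list",
                 trials = "list", nFolds = "integer")
)

#' Result of a two-stage voxel selection
#'
#' First stage: the \code{kActivated} voxels most correlated (in absolute
#' value) with the simulated BOLD regressor on the training rows. Second
#' stage: the \code{kInformative} voxels with the largest mean absolute
#' sparse-representation coefficient, accumulated over repeated L1-minimizing
#' linear programs on random voxel subsets.
#'
#' @slot selectionCondition condition whose data drove the selection
#' @slot fold cross-validation fold whose training rows were used
#' @slot activated global voxel indices that passed correlation screening
#' @slot informative global voxel indices selected by sparse representation
#' @slot weights mean absolute LP coefficient per activated voxel
#' @slot rounds number of LP rounds in which each activated voxel was drawn
#' @slot params list of selection parameters (k, rounds, subset size, eps, seed)
#'
#' @name VoxelSelection-class
#' @exportClass VoxelSelection
setClass("VoxelSelection",
  representation(selectionCondition = "character", fold = "integer",
                 activated = "integer", informative = "integer",
                 weights = "numeric", rounds = "integer", params = "list")
)

setValidity("VoxelSelection", function(object) {
  msg <- NULL
  if (!all(object@informative %in% object@activated))
    msg <- c(msg, "informative voxels must be a subset of activated voxels")
  if (length(object@weights) != length(object@activated))
    msg <- c(msg, "one weight per activated voxel required")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' A set of per-trial brain pattern vectors at a fixed trial time point
#'
#' Each row of \code{patterns} is the vector of signal values over the
#' selected voxels for one trial, sampled at within-trial time point
#' \code{timePoint} (1 = trial onset sample, in TR steps).
#'
#' @slot patterns trials x voxels matrix of pattern vectors
#' @slot category semantic category of each trial
#' @slot trial trial index of each pattern
#' @slot timePoint within-trial sample index (1-based)
#' @slot condition stimulus condition of the test data
#' @slot voxels global voxel indices the patterns are defined over
#'
#' @name PatternSet-class
#' @exportClass PatternSet
setClass("PatternSet",
  representation(patterns = "matrix", category = "character",
                 trial = "integer", timePoint = "integer",
                 condition = "character", voxels = "integer")
)

setValidity("PatternSet", function(object) {
  msg <- NULL
  if (nrow(object@patterns) != length(object@category) ||
      nrow(object@patterns) != length(object@trial))
    msg <- c(msg, "one category and trial index per pattern required")
  if (ncol(object@patterns) != length(object@voxels))
    msg <- c(msg, "pattern dimension must match the voxel set")
  if (!all(is.finite(object@patterns)))
    msg <- c(msg, "patterns must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Cubic region of interest in Talairach coordinates
#'
#' @slot center cube center, Talairach millimetres (x, y, z)
#' @slot halfWidth half the edge length, millimetres
#' @slot side label for the ROI (e.g. "left", "right")
#'
#' @name RoiSpec-class
#' @exportClass RoiSpec
setClass("RoiSpec",
  representation(center = "numeric", halfWidth = "numeric", side = "character")
)

setValidity("RoiSpec", function(object) {
  if (length(object@center) != 3L) return("center must be (x, y, z)")
  if (object@halfWidth <= 0) return("halfWidth must be positive")
  TRUE
})

#' Per-subject fMRI dataset as a SummarizedExperiment
#'
#' Rows (features) are voxels; columns (samples) are acquired volumes in time
#' order. \code{rowData} holds voxel coordinates and, for synthetic data, the
#' planted ground truth; \code{colData} holds the run, acquisition time and
#' trial/condition/category of each sample; \code{metadata} holds the
#' \linkS4class{ExperimentDesign} and the event table.
#'
#' @name FmriExperiment-class
#' @exportClass FmriExperiment
setClass("FmriExperiment", contains = "SummarizedExperiment")

setValidity("FmriExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("run", "sample_time", "trial_index", "condition", "category")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  r <- cd$run
  if (any(r != cummax(r))) return("run blocks must be contiguous and ordered")
  TRUE
})

#' Parameters of the analysis pipeline
#'
#' Bundles the tunable constants of the full analysis: the two selection
#' stage sizes, the sparse-representation LP schedule, pattern time points,
#' decoding settings and ROI parameters. Defaults are the reference
#' whole-brain protocol (1500 activated, 500 informative voxels, 200 LP
#' rounds of 400-voxel subsets).
#'
#' @slot kActivated voxels kept by correlation screening
#' @slot kInformative voxels kept by sparse-representation selection
#' @slot nRounds number of LP rounds per selection
#' @slot subsetSize voxels drawn per LP round
#' @slot epsFactor LP residual tolerance, as a fraction of max(abs(labeled regressor))
#' @slot tPoints within-trial time points at which patterns are extracted
#' @slot decodeT time point used for decoding features
#' @slot svmCost SVM regularization constant C
#' @slot reproVariant "mean-cosine" or "mean-angle" form of the index
#' @slot roiM activated voxels per condition entering the ROI intersection
#' @slot roiSpecs list of \linkS4class{RoiSpec}
#' @slot nFolds cross-validation folds
#'
#' @name AnalysisParams-class
#' @exportClass AnalysisParams
setClass("AnalysisParams",
  representation(kActivated = "integer", kInformative = "integer",
                 nRounds = "integer", subsetSize = "integer",
                 epsFactor = "numeric", tPoints = "integer",
                 decodeT = "integer", svmCost = "numeric",
                 reproVariant = "character", roiM = "integer",
                 roiSpecs = "list", nFolds = "integer")
)

#' Configuration of the synthetic-data generator
#'
#' Defines the statistical structure of a simulated subject: a sparse set of
#' category-informative voxels with signed effects, a shared stimulus-locked
#' activation response in every voxel, condition-dependent within-class
#' dispersion of the informative pattern (trial-level multiplicative jitter),
#' i.i.d. Gaussian measurement noise, per-run linear drift, and Talairach
#' coordinates placing a fixed number of informative voxels inside each
#' STS/MTG cube.
#'
#' @slot nVoxels total voxels
#' @slot nInformative planted category-informative voxels
#' @slot nRoiPerSide informative voxels placed inside each ROI cube
#' @slot categoryAmplitude named vector, condition -> category effect size
#' @slot withinClassDispersion named vector, condition -> sd of the trial-level
#'   multiplicative jitter on the informative pattern
#' @slot noiseSd sd of the additive per-sample measurement noise
#' @slot activationAmplitude shared stimulus-locked response amplitude
#' @slot baseline mean raw signal level added to every voxel
#' @slot driftSd sd of the per-voxel linear drift amplitude per run
#' @slot seed integer seed for the subject
#'
#' @name SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nVoxels = "integer", nInformative = "integer",
                 nRoiPerSide = "integer", categoryAmplitude = "numeric",
                 withinClassDispersion = "numeric", noiseSd = "numeric",
                 activationAmplitude = "numeric", baseline = "numeric",
                 driftSd = "numeric", seed = "integer")
)

setValidity("SyntheticConfig", function(object) {
  msg <- NULL
  if (object@nInformative > object@nVoxels)
    msg <- c(msg, "nInformative must not exceed nVoxels")
  if (2L * object@nRoiPerSide > object@nInformative)
    msg <- c(msg, "2 * nRoiPerSide must not exceed nInformative")
  amps <- c(object@categoryAmplitude, object@withinClassDispersion,
            object@noiseSd, object@activationAmplitude, object@driftSd)
  if (any(!is.finite(amps)) || any(amps < 0))
    msg <- c(msg, "amplitudes and standard deviations must be finite and >= 0")
  if (is.null(msg)) TRUE else msg
})
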