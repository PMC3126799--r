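#' Cubic Talairach ROI specifications
#'
#' \code{RoiSpec} builds one cubic region of interest; \code{stsMtgRois}
#' returns the default pair used for audiovisual integration analyses: cubes
#' of half-width 15 mm centered on the left and right superior temporal
#' sulcus / middle temporal gyrus at Talairach (-55, -40, 7) and (55, -40, 7).
#'
#' @param center cube center (x, y, z), Talairach mm
#' @param halfWidth half edge length, mm
#' @param side label
#' @return an \linkS4class{RoiSpec}, or a list of two for \code{stsMtgRois}
#' @export
RoiSpec <- function(center, halfWidth = 15, side = "roi") {
  new("RoiSpec", center = as.numeric(center),
      halfWidth = as.numeric(halfWidth), side = as.character(side))
}

#' @rdname RoiSpec
#' @param a half-width of the cubes, mm
#' @export
stsMtgRois <- function(a = 15) {
  list(left = RoiSpec(c(-55, -40, 7), a, "left"),
       right = RoiSpec(c(55, -40, 7), a, "right"))
}

setMethod("show", "RoiSpec", function(object) {
  cat("RoiSpec (", object@side, "): cube ", sep = "")
  cat(paste(sprintf("[%g, %g]", object@center - object@halfWidth,
                    object@center + object@halfWidth), collapse = " x "), "\n")
})

#' Voxels inside a cubic ROI (closed bounds)
#'
#' @param coords voxels x 3 coordinate matrix, Talairach mm
#' @param spec an \linkS4class{RoiSpec}
#' @return logical vector over voxels
#' @export
inRoiCube <- function(coords, spec) {
  lo <- spec@center - spec@halfWidth
  hi <- spec@center + spec@halfWidth
  coords[, 1] >= lo[1] & coords[, 1] <= hi[1] &
    coords[, 2] >= lo[2] & coords[, 2] <= hi[2] &
    coords[, 3] >= lo[3] & coords[, 3] <= hi[3]
}

#' Select ROI voxels active under every stimulus condition
#'
#' Per condition, the \code{m} voxels with the largest absolute correlation
#' between their full time series in that condition (all trials) and the
#' simulated BOLD regressor are marked active; the four per-condition sets
#' are intersected, and the intersection is filtered to the voxels whose
#' Talairach coordinates fall inside the ROI cube (closed bounds).
#'
#' @param values preprocessed samples x voxels matrix
#' @param regressors a \linkS4class{BoldRegressors}
#' @param partition a \linkS4class{ConditionPartition}
#' @param coords voxels x 3 Talairach coordinates
#' @param spec an \linkS4class{RoiSpec}
#' @param m active voxels per condition
#' @return integer voxel indices of the ROI set
#' @export
roiSelect <- function(values, regressors, partition, coords, spec, m = 3000L) {
  if (nrow(coords) != ncol(values))
    stop("coordinates required for every voxel")
  active <- lapply(conditionNames(partition), function(cc) {
    rows <- conditionRows(partition, cc)
    selectActivated(values[rows, , drop = FALSE], regressors@hs[rows],
                    k = min(m, ncol(values)))$activated
  })
  common <- Reduce(intersect, active)
  roi <- common[inRoiCube(coords[common, , drop = FALSE], spec)]
  if (length(roi) == 0)
    stop("empty ROI: no commonly active voxel inside the ", spec@side,
         " cube")
  sort(roi)
}

#' Reproducibility and norm statistics within anatomical ROIs
#'
#' Runs \code{\link{roiSelect}} for each ROI and computes, per stimulus
#' condition, category and trial time point, the reproducibility index and
#' average pattern norm over all trials of the condition.
#'
#' @inheritParams roiSelect
#' @param specs list of \linkS4class{RoiSpec}
#' @param tPoints within-trial time points
#' @param variant reproducibility index variant
#' @return a data.frame with one row per (side, condition, category, t)
#' @export
roiAnalysis <- function(values, regressors, partition, coords, specs,
                        m = 3000L, tPoints = 3L, variant = "mean-cosine") {
  out <- list()
  for (spec in specs) {
    roi <- roiSelect(values, regressors, partition, coords, spec, m)
    for (cc in conditionNames(partition)) {
      for (t in tPoints) {
        ps <- extractPatterns(values, roi, partition, cc, t)
        R <- reproducibilityIndex(ps, variant)
        N <- averageNorm(ps)
        out[[length(out) + 1L]] <- data.frame(
          side = spec@side, condition = cc, category = names(R), t = t,
          R = unname(R), N = unname(N), n_voxels = length(roi),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
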