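#' Preprocessing: masking, per-run standardization, per-run detrending
#'
#' \code{applyMask} restricts the matrix to a voxel subset (column order
#' preserved). \code{zscoreRuns} standardizes every voxel within every run to
#' zero mean and unit population variance (1/N); voxels constant within a run
#' are set to zero with a warning. \code{detrendRuns} removes the
#' least-squares linear trend from every voxel within every run. The
#' conventional order is mask, then z-score, then detrend
#' (\code{preprocessDataset}).
#'
#' @param x an \linkS4class{FmriExperiment}, or a numeric samples x voxels
#'   matrix (matrix methods take the run vector via \code{attr(x, "run")} or
#'   treat all rows as one run)
#' @param mask integer voxel indices (or logical vector) to keep
#' @return object of the same class as \code{x}
#' @name preprocess
NULL

zscoreMatrixRuns <- function(values, run) {
  warned <- FALSE
  for (r in unique(run)) {
    sel <- run == r
    v <- values[sel, , drop = FALSE]
    m <- colMeans(v)
    sdv <- sqrt(colMeans(v * v) - m * m)
    const <- sdv <= 0 | !is.finite(sdv)
    if (any(const) && !warned) {
      warning(sum(const), " voxel(s) constant within run ", r,
              "; set to zero")
      warned <- TRUE
    }
    sdv[const] <- 1
    v <- sweep(sweep(v, 2L, m, "-"), 2L, sdv, "/")
    v[, const] <- 0
    values[sel, ] <- v
  }
  values
}

detrendMatrixRuns <- function(values, run) {
  for (r in unique(run)) {
    sel <- run == r
    v <- values[sel, , drop = FALSE]
    n <- nrow(v)
    tt <- seq_len(n) - (n + 1) / 2          # centered time index
    stt <- sum(tt * tt)
    beta <- crossprod(tt, v) / stt           # slope per voxel
    mu <- colMeans(v)
    values[sel, ] <- v - outer(rep(1, n), mu) - outer(tt, drop(beta))
  }
  values
}

#' @rdname preprocess
#' @export
setMethod("applyMask", "FmriExperiment", function(x, mask) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("mask must not be empty")
  if (any(mask < 1 | mask > nrow(x)))
    stop("mask refers to unknown voxel(s)")
  x[mask, ]
})

#' @rdname preprocess
#' @export
setMethod("zscoreRuns", "FmriExperiment", function(x)
  setBoldMatrix(x, zscoreMatrixRuns(boldMatrix(x), runIds(x))))

#' @rdname preprocess
#' @export
setMethod("detrendRuns", "FmriExperiment", function(x)
  setBoldMatrix(x, detrendMatrixRuns(boldMatrix(x), runIds(x))))

#' @rdname preprocess
#' @export
setMethod("zscoreRuns", "matrix", function(x) {
  run <- attr(x, "run")
  if (is.null(run)) run <- rep(1L, nrow(x))
  out <- zscoreMatrixRuns(x, run)
  attr(out, "run") <- run
  out
})

#' @rdname preprocess
#' @export
setMethod("detrendRuns", "matrix", function(x) {
  run <- attr(x, "run")
  if (is.null(run)) run <- rep(1L, nrow(x))
  out <- detrendMatrixRuns(x, run)
  attr(out, "run") <- run
  out
})

#' @rdname preprocess
#' @export
setMethod("applyMask", "matrix", function(x, mask) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("mask must not be empty")
  if (any(mask < 1 | mask > ncol(x))) stop("mask refers to unknown voxel(s)")
  run <- attr(x, "run")
  out <- x[, mask, drop = FALSE]
  attr(out, "run") <- run
  out
})

#' @rdname preprocess
#' @export
preprocessDataset <- function(x, mask = NULL) {
  if (!is.null(mask)) x <- applyMask(x, mask)
  detrendRuns(zscoreRuns(x))
}
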