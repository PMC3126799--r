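#' Extract per-trial brain pattern vectors at a trial time point
#'
#' For each trial of \code{condition} (restricted to one fold if \code{fold}
#' is given), the pattern vector is the data row at the trial's
#' \code{t}-th acquired sample (t = 1 is the sample at trial onset),
#' restricted to \code{voxels}.
#'
#' @param values samples x voxels data matrix (all rows)
#' @param voxels global voxel indices defining the pattern space
#' @param partition a \linkS4class{ConditionPartition}
#' @param condition test condition
#' @param t within-trial time point, in 1..samples per trial
#' @param fold optional test fold; \code{NULL} uses all trials
#' @return a \linkS4class{PatternSet}
#' @export
extractPatterns <- function(values, voxels, partition, condition, t,
                            fold = NULL) {
  ti <- trialInfo(partition, condition)
  spt <- length(conditionRows(partition, condition)) / nrow(ti)
  if (!t %in% seq_len(spt))
    stop("t must be in 1..", spt)
  if (!is.null(fold)) ti <- ti[ti$fold == fold, , drop = FALSE]
  rows <- ti$start_row + (t - 1L)
  new("PatternSet",
      patterns = values[rows, voxels, drop = FALSE],
      category = ti$category, trial = as.integer(ti$trial_index),
      timePoint = as.integer(t), condition = condition,
      voxels = as.integer(voxels))
}

#' @describeIn extractPatterns the trials x voxels pattern matrix
#' @param x a PatternSet
#' @export
setMethod("patternMatrix", "PatternSet", function(x) x@patterns)

setMethod("categoryNames", "PatternSet", function(x) unique(x@category))

setMethod("show", "PatternSet", function(object) {
  cat("PatternSet: ", nrow(object@patterns), " trials x ",
      ncol(object@patterns), " voxels (condition ", object@condition,
      ", t = ", object@timePoint, ")\n", sep = "")
  print(table(object@category))
})

reproCore <- function(X, variant = c("mean-cosine", "mean-angle")) {
  variant <- match.arg(variant)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 patterns")
  nrm <- sqrt(rowSums(X * X))
  if (any(nrm == 0))
    stop("zero-norm pattern in trial(s) ",
         paste(which(nrm == 0), collapse = ", "))
  Xn <- X / nrm
  C <- tcrossprod(Xn)
  off <- C[upper.tri(C)]
  if (variant == "mean-cosine") mean(off)
  else cos(mean(acos(pmin(1, pmax(-1, off)))))
}

#' Pattern reproducibility index
#'
#' The within-class reproducibility index of a set of pattern vectors is the
#' mean cosine of the angle between every pair of vectors,
#' \deqn{R = \frac{2}{n(n-1)} \sum_{i<j} \frac{\langle x_i, x_j \rangle}
#' {\|x_i\| \|x_j\|}.}
#' It is 1 for identical directions, 0 for orthogonal ones, and invariant to
#' per-pattern positive rescaling. The alternative \code{"mean-angle"}
#' variant returns the cosine of the mean pairwise angle; both variants order
#' any two pattern sets identically.
#'
#' For a \linkS4class{PatternSet} the index is computed per semantic
#' category and returned as a named vector.
#'
#' @param x a patterns x voxels matrix (one category), or a
#'   \linkS4class{PatternSet}
#' @param variant "mean-cosine" (default) or "mean-angle"
#' @param ... passed through
#' @return scalar in [-1, 1], or a named vector for a PatternSet
#' @examples
#' reproducibilityIndex(rbind(c(1, 0), c(1, 1), c(0, 1)))  # ~0.4714
#' @export
setMethod("reproducibilityIndex", "matrix",
          function(x, variant = c("mean-cosine", "mean-angle"), ...)
            reproCore(x, variant))

#' @rdname reproducibilityIndex-matrix-method
#' @export
setMethod("reproducibilityIndex", "PatternSet",
          function(x, variant = c("mean-cosine", "mean-angle"), ...) {
  cats <- sort(unique(x@category))
  vapply(setNames(cats, cats), function(g)
    reproCore(x@patterns[x@category == g, , drop = FALSE], variant),
    numeric(1))
})

#' Average pattern norm
#'
#' Mean Euclidean length of the pattern vectors, \eqn{N = \frac{1}{n}
#' \sum_i \|x_i\|}; a proxy for overall signal level. For a
#' \linkS4class{PatternSet} the norm is computed per semantic category.
#'
#' @param x a patterns x voxels matrix, or a \linkS4class{PatternSet}
#' @param ... unused
#' @return scalar >= 0, or a named vector for a PatternSet
#' @export
setMethod("averageNorm", "matrix", function(x, ...)
  mean(sqrt(rowSums(x * x))))

#' @rdname averageNorm-matrix-method
#' @export
setMethod("averageNorm", "PatternSet", function(x, ...) {
  cats <- sort(unique(x@category))
  vapply(setNames(cats, cats), function(g)
    averageNorm(x@patterns[x@category == g, , drop = FALSE]), numeric(1))
})

#' Trial-wise difference patterns against a baseline time point
#'
#' Subtracts, per trial, the baseline pattern (by default the trial-onset
#' sample, t = 1, which carries no stimulus-evoked information yet) from the
#' pattern at the later time point. Average norms of difference patterns
#' isolate the evoked signal change from the shared baseline.
#'
#' @param x a \linkS4class{PatternSet}
#' @param baseline a \linkS4class{PatternSet} on the same trials and voxels
#' @return a \linkS4class{PatternSet} of difference patterns
#' @export
differencePatterns <- function(x, baseline) {
  if (!identical(x@trial, baseline@trial))
    stop("pattern sets cover different trials")
  if (!identical(x@voxels, baseline@voxels))
    stop("pattern sets cover different voxels")
  new("PatternSet", patterns = x@patterns - baseline@patterns,
      category = x@category, trial = x@trial, timePoint = x@timePoint,
      condition = x@condition, voxels = x@voxels)
}
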