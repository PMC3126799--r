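#' Minimum-L1-norm fit under a uniform residual bound (basis pursuit)
#'
#' Solves \deqn{\min_w \|w\|_1 \quad s.t. \quad \|A w - y\|_\infty \le
#' \epsilon} as a linear program by variable splitting, using a primal-dual
#' interior-point method. With \code{eps = 0} the constraint becomes the
#' exact linear system \eqn{A w = y}. An explicit error is raised when the
#' constraint set is empty (\code{eps} smaller than the best achievable
#' uniform residual of an inconsistent overdetermined system).
#'
#' @param A numeric matrix (rows x coefficients)
#' @param y numeric response vector, \code{length(y) == nrow(A)}
#' @param eps residual bound, >= 0
#' @param tol interior-point convergence tolerance
#' @param maxit maximum interior-point iterations
#' @return the coefficient vector \code{w}, with attributes \code{status},
#'   \code{iterations} and \code{l1} (its L1 norm)
#' @examples
#' w <- l1MinFit(diag(3), c(1, 2, 3), eps = 0)
#' round(w, 6)
#' @export
l1MinFit <- function(A, y, eps, tol = 1e-8, maxit = 200L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  y <- as.numeric(y)
  if (nrow(A) != length(y)) stop("nrow(A) must equal length(y)")
  if (!all(is.finite(A)) || !all(is.finite(y))) stop("inputs must be finite")
  if (!is.finite(eps) || eps < 0) stop("eps must be finite and >= 0")
  if (all(abs(y) <= eps)) {
    # w = 0 is feasible and has minimal norm
    w <- numeric(ncol(A))
  } else {
    fit <- if (eps == 0) cpp_l1_eq(A, y, tol, maxit)
           else cpp_l1_ineq(A, y, eps, tol, maxit)
    if (fit$status == "infeasible")
      stop("l1MinFit: constraints infeasible (eps too small for an ",
           "inconsistent overdetermined system)")
    if (fit$status != "optimal" && fit$status != "maxit")
      stop("l1MinFit: solver failed with status ", fit$status)
    if (fit$status == "maxit" &&
        (fit$primal_infeasibility > 1e-6 || fit$mu > 1e-6))
      stop("l1MinFit: no convergence within ", maxit, " iterations")
    w <- as.numeric(fit$w)
    attr(w, "status") <- fit$status
    attr(w, "iterations") <- fit$iterations
  }
  # snap solver noise below the duality-gap scale to exact zero
  w[abs(w) < 1e-10 * max(1, max(abs(w)))] <- 0
  attr(w, "l1") <- sum(abs(w))
  w
}

#' Correlation screening of activated voxels
#'
#' Ranks voxels by the absolute Pearson correlation between their training
#' time series and the simulated BOLD regressor, and keeps the top \code{k}.
#' Zero-variance voxels get correlation 0 and rank last; ties are broken by
#' voxel index for determinism.
#'
#' @param train training samples x voxels matrix
#' @param hs simulated BOLD regressor on the same rows
#' @param k number of voxels to keep
#' @return list with \code{r} (signed correlation per voxel), \code{ranking}
#'   (all voxel indices, most activated first) and \code{activated} (top k)
#' @export
selectActivated <- function(train, hs, k) {
  if (k > ncol(train)) stop("k exceeds the number of voxels")
  if (nrow(train) != length(hs)) stop("hs must match the training rows")
  r <- suppressWarnings(as.numeric(cor(train, hs)))
  r[!is.finite(r)] <- 0
  ranking <- order(-abs(r), seq_along(r))
  list(r = r, ranking = ranking, activated = sort(ranking[seq_len(k)]))
}

#' Sparse-representation selection of informative voxels
#'
#' Iteratively builds per-voxel sparse-coefficient scores: in each round a
#' random subset of \code{subsetSize} voxels is drawn without replacement,
#' the labeled BOLD regressor is represented by the subset's training time
#' series via the L1-minimizing linear program \code{\link{l1MinFit}}, and
#' the absolute coefficients are accumulated. Voxels are ranked by the mean
#' absolute coefficient over the rounds in which they were drawn (never-drawn
#' voxels score 0); the top \code{k} form the informative set. Ties at the
#' cutoff are broken by voxel index.
#'
#' The residual bound of each round is \code{epsFactor * max(abs(hl))},
#' raised if necessary to just above the subset's least-squares residual so
#' that every round's program is feasible (relevant only when the subset has
#' fewer voxels than training samples).
#'
#' @param train training samples x activated-voxels matrix
#' @param hl labeled BOLD regressor on the same rows
#' @param k number of informative voxels to select
#' @param nRounds number of LP rounds
#' @param subsetSize voxels per round
#' @param epsFactor residual bound as a fraction of \code{max(abs(hl))}
#' @param seed integer seed for the subset draws
#' @param voxelIds optional global ids of the columns of \code{train}
#' @param selectionCondition,fold bookkeeping labels stored in the result
#' @return a \linkS4class{VoxelSelection}
#' @export
sparseSelect <- function(train, hl, k, nRounds = 200L, subsetSize = 400L,
                         epsFactor = 0.1, seed = 1L, voxelIds = NULL,
                         selectionCondition = NA_character_, fold = NA_integer_) {
  nv <- ncol(train)
  if (subsetSize > nv)
    stop("subsetSize exceeds the number of available voxels")
  if (k > nv) stop("k exceeds the number of available voxels")
  if (all(hl == 0)) stop("labeled regressor is identically zero")
  if (nrow(train) != length(hl)) stop("hl must match the training rows")
  if (is.null(voxelIds)) voxelIds <- seq_len(nv)
  epsBase <- epsFactor * max(abs(hl))
  scores <- numeric(nv)
  rounds <- integer(nv)
  withSeed(seed, {
    for (it in seq_len(nRounds)) {
      idx <- sample.int(nv, subsetSize)
      A <- train[, idx, drop = FALSE]
      eps <- epsBase
      if (subsetSize < nrow(train)) {
        # guarantee feasibility: the least-squares solution is a witness
        res <- qr.resid(qr(A), hl)
        eps <- max(eps, 1.02 * max(abs(res)))
      }
      w <- tryCatch(l1MinFit(A, hl, eps), error = function(e) NULL)
      if (is.null(w))   # rare numerical failure: retry with a looser bound
        w <- l1MinFit(A, hl, eps * 1.25)
      scores[idx] <- scores[idx] + abs(w)
      rounds[idx] <- rounds[idx] + 1L
    }
  })
  mean_w <- ifelse(rounds > 0L, scores / pmax(rounds, 1L), 0)
  ord <- order(-mean_w, seq_len(nv))
  top <- sort(ord[seq_len(k)])
  new("VoxelSelection",
      selectionCondition = selectionCondition, fold = as.integer(fold),
      activated = as.integer(voxelIds),
      informative = as.integer(voxelIds[top]),
      weights = mean_w, rounds = rounds,
      params = list(k = k, nRounds = nRounds, subsetSize = subsetSize,
                    epsFactor = epsFactor, seed = seed))
}

#' Two-stage voxel selection for one condition and fold
#'
#' Runs correlation screening (stage 1) followed by sparse-representation
#' selection (stage 2) on the training rows of one condition/fold, using only
#' data outside the test fold.
#'
#' @param values preprocessed samples x voxels matrix (all rows)
#' @param regressors a \linkS4class{BoldRegressors}
#' @param partition a \linkS4class{ConditionPartition}
#' @param condition selection condition
#' @param fold test fold excluded from training
#' @param params an \linkS4class{AnalysisParams}
#' @param seed seed for the LP subset draws
#' @return a \linkS4class{VoxelSelection} with global voxel indices
#' @export
runSelection <- function(values, regressors, partition, condition, fold,
                         params, seed = 1L) {
  rows <- foldRows(partition, condition, fold, "train")
  train <- values[rows, , drop = FALSE]
  act <- selectActivated(train, regressors@hs[rows], params@kActivated)
  sparseSelect(train[, act$activated, drop = FALSE], regressors@hl[rows],
               k = params@kInformative, nRounds = params@nRounds,
               subsetSize = params@subsetSize, epsFactor = params@epsFactor,
               seed = seed, voxelIds = act$activated,
               selectionCondition = condition, fold = fold)
}

#' @describeIn runSelection voxels passing correlation screening
#' @param x a VoxelSelection
#' @export
setMethod("activatedVoxels", "VoxelSelection", function(x) x@activated)

#' @describeIn runSelection the informative voxel set
#' @export
setMethod("selectedVoxels", "VoxelSelection", function(x) x@informative)

setMethod("show", "VoxelSelection", function(object) {
  cat("VoxelSelection (", object@selectionCondition, ", fold ",
      object@fold, "): ", length(object@informative), " informative of ",
      length(object@activated), " activated voxels\n", sep = "")
})

#' Serialize a voxel selection as CSV (+ JSON parameter sidecar)
#'
#' @param sel a \linkS4class{VoxelSelection}
#' @param path output CSV path; the sidecar is written to
#'   \code{paste0(path, ".json")} when the jsonlite package is available
#' @export
writeSelection <- function(sel, path) {
  ord <- order(-sel@weights, seq_along(sel@weights))
  df <- data.frame(voxel_id = sel@activated,
                   score = sel@weights,
                   rank = order(ord),
                   selected = sel@activated %in% sel@informative)
  write.csv(df[ord, ], path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      c(sel@params, list(selection_condition = sel@selectionCondition,
                         fold = sel@fold)),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
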