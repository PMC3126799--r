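#' Build decoding feature vectors from selected voxels
#'
#' One feature vector per trial: the signal values of the informative voxel
#' set at within-trial time point \code{t} (default 3). With
#' \code{normalize = TRUE} every feature vector is rescaled to unit Euclidean
#' length, which removes pattern-norm information from the classifier input.
#'
#' @param values preprocessed samples x voxels matrix
#' @param voxels informative voxel indices
#' @param partition a \linkS4class{ConditionPartition}
#' @param condition training/testing condition
#' @param fold test fold
#' @param which "train" (all other folds) or "test" (the fold itself)
#' @param t within-trial time point
#' @param normalize rescale each feature vector to length 1
#' @return list with matrix \code{x}, factor \code{y} and \code{trial}
#' @export
makeFeatures <- function(values, voxels, partition, condition, fold,
                         which = c("train", "test"), t = 3L,
                         normalize = FALSE) {
  which <- match.arg(which)
  ti <- trialInfo(partition, condition)
  keep <- if (which == "test") ti$fold == fold else ti$fold != fold
  ti <- ti[keep, , drop = FALSE]
  x <- values[ti$start_row + (t - 1L), voxels, drop = FALSE]
  if (normalize) {
    nrm <- sqrt(rowSums(x * x))
    if (any(nrm == 0)) stop("cannot normalize a zero feature vector")
    x <- x / nrm
  }
  list(x = x, y = factor(ti$category), trial = ti$trial_index)
}

#' Train a linear SVM and predict held-out trials
#'
#' Fits a maximum-margin linear classifier (hinge loss, L2 penalty, constant
#' \code{cost}) on the training features and reports per-trial predictions
#' and percent accuracy on the test features. A decision value of exactly
#' zero is resolved to the first factor level for determinism.
#'
#' @param train,test feature lists from \code{\link{makeFeatures}}
#' @param cost SVM regularization constant C
#' @return list with \code{predictions}, \code{accuracy} (percent),
#'   \code{decisionValues} and \code{nTest}
#' @export
trainAndPredict <- function(train, test, cost = 1) {
  lev <- levels(train$y)
  if (length(unique(as.character(train$y))) < 2)
    stop("training set must contain both categories")
  fit <- e1071::svm(train$x, train$y, kernel = "linear", cost = cost,
                    scale = FALSE)
  pr <- predict(fit, test$x, decision.values = TRUE)
  dvm <- attr(pr, "decision.values")
  dv <- drop(dvm)
  # libsvm orients the decision value toward the class named first in the
  # "A/B" column label; map it back to our factor levels explicitly
  pos <- strsplit(colnames(dvm)[1], "/")[[1]][1]
  predPos <- dv >= 0
  pred <- ifelse(predPos, pos, setdiff(lev, pos))
  acc <- 100 * mean(pred == as.character(test$y))
  list(predictions = factor(pred, levels = lev), accuracy = acc,
       decisionValues = dv, nTest = length(pred))
}

#' Cross-validated decoding grid over selection and test conditions
#'
#' For every voxel selection (selection condition x fold) and every
#' training/testing condition, trains the linear SVM on the training folds
#' and predicts the held-out fold, for raw and/or unit-normalized feature
#' vectors. Selection and classifier training never see the test fold.
#'
#' @param values preprocessed samples x voxels matrix
#' @param selections list of \linkS4class{VoxelSelection} (one per selection
#'   condition and fold)
#' @param partition a \linkS4class{ConditionPartition}
#' @param t feature time point
#' @param variants subset of c("raw", "normalized")
#' @param cost SVM constant C
#' @return data.frame with one row per (variant, selection condition, test
#'   condition, fold): accuracy (percent), test size, and the number of test
#'   trials predicted as each category
#' @export
decodingGrid <- function(values, selections, partition, t = 3L,
                         variants = c("raw", "normalized"), cost = 1) {
  out <- list()
  for (sel in selections) {
    vox <- selectedVoxels(sel)
    for (cc in conditionNames(partition)) {
      for (variant in variants) {
        nrm <- variant == "normalized"
        train <- makeFeatures(values, vox, partition, cc, sel@fold, "train",
                              t, normalize = nrm)
        test <- makeFeatures(values, vox, partition, cc, sel@fold, "test",
                             t, normalize = nrm)
        fit <- trainAndPredict(train, test, cost)
        lev <- levels(fit$predictions)
        out[[length(out) + 1L]] <- data.frame(
          variant = variant,
          selection_condition = sel@selectionCondition,
          test_condition = cc, fold = sel@fold,
          accuracy = fit$accuracy, n_test = fit$nTest,
          n_pred_first = sum(fit$predictions == lev[1]),
          n_pred_second = sum(fit$predictions == lev[2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
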