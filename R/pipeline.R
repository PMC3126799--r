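#' Analysis parameters
#'
#' Defaults are the reference whole-brain protocol: correlation screening to
#' 1500 activated voxels, sparse-representation selection of 500 informative
#' voxels via 400 LP rounds of 100-voxel subsets, patterns at trial time
#' points 1..5, decoding features at t = 4 (the acquisition nearest 6 s
#' after the first stimulus onset, where the evoked response peaks) with a
#' linear SVM (C = 1), and ROI analysis with 3000 active voxels per
#' condition intersected over the four conditions inside the STS/MTG cubes.
#'
#' @param kActivated,kInformative selection stage sizes
#' @param nRounds,subsetSize,epsFactor sparse-representation LP schedule
#' @param tPoints pattern time points
#' @param decodeT decoding feature time point
#' @param svmCost SVM constant C
#' @param reproVariant reproducibility index variant
#' @param roiM,roiSpecs ROI analysis settings
#' @param nFolds cross-validation folds
#' @return an \linkS4class{AnalysisParams}
#' @export
analysisParams <- function(kActivated = 1500L, kInformative = 500L,
                           nRounds = 400L, subsetSize = 100L,
                           epsFactor = 0.1, tPoints = 1:5, decodeT = 4L,
                           svmCost = 1, reproVariant = "mean-cosine",
                           roiM = 3000L, roiSpecs = stsMtgRois(),
                           nFolds = 4L) {
  new("AnalysisParams",
      kActivated = as.integer(kActivated),
      kInformative = as.integer(kInformative),
      nRounds = as.integer(nRounds), subsetSize = as.integer(subsetSize),
      epsFactor = as.numeric(epsFactor), tPoints = as.integer(tPoints),
      decodeT = as.integer(decodeT), svmCost = as.numeric(svmCost),
      reproVariant = as.character(reproVariant), roiM = as.integer(roiM),
      roiSpecs = roiSpecs, nFolds = as.integer(nFolds))
}

setMethod("show", "AnalysisParams", function(object) {
  cat("AnalysisParams: screen to", object@kActivated,
      "voxels, sparse-select", object@kInformative, "\n")
  cat("  LP rounds:", object@nRounds, "x subsets of", object@subsetSize,
      "voxels, eps factor", object@epsFactor, "\n")
  cat("  patterns at t =", paste(object@tPoints, collapse = ","),
      "; decoding at t =", object@decodeT, "(C =", object@svmCost, ")\n")
})

#' Desk-scale simulation protocol
#'
#' A reduced problem size for simulation studies that preserves the reference
#' protocol's structure (same design: 320 trials, 1600 samples, 4 folds) and
#' its stage-size ratios, while keeping a full per-subject run to a few
#' seconds: 800 voxels, screening to 200 (25 percent, as 1500/6000),
#' sparse-selecting 80 via 60 LP rounds of 40-voxel subsets, ROI
#' intersection over the top half of voxels per condition.
#'
#' @param seed cohort/subject seed
#' @param ... overrides forwarded to \code{\link{syntheticConfig}} (e.g.
#'   \code{categoryAmplitude = 0} for a null cohort)
#' @return list with elements \code{design}, \code{config}, \code{params}
#' @export
deskScaleProtocol <- function(seed = 1L, ...) {
  design <- ExperimentDesign()
  list(design = design,
       config = syntheticConfig(nVoxels = 800L, nInformative = 60L,
                                nRoiPerSide = 30L, seed = seed,
                                design = design, ...),
       params = analysisParams(kActivated = 200L, kInformative = 80L,
                               nRounds = 60L, subsetSize = 40L, roiM = 400L))
}

#' Run the full analysis for one subject
#'
#' Preprocesses the data (per-run z-scoring and detrending), builds the BOLD
#' regressors and the condition partition, performs the two-stage voxel
#' selection for every selection condition and fold, and computes the
#' reproducibility/norm grid, the decoding grid, and (when coordinates are
#' available) the ROI statistics. Selection and classifier training use only
#' training folds.
#'
#' @param dataset an \linkS4class{FmriExperiment} (raw; preprocessing is
#'   applied internally)
#' @param params an \linkS4class{AnalysisParams}
#' @param seed subject-level seed for the LP subset draws
#' @param roi run the ROI analysis (requires voxel coordinates)
#' @return list with data.frames \code{reproducibility} (one row per
#'   selection condition x fold x test condition x category x t, with R, N
#'   and the difference-pattern norm against t = 1) and \code{decoding}, the
#'   \code{roi} table or NULL, the \code{selections}, and the partition
#' @export
runSubject <- function(dataset, params = analysisParams(), seed = 1L,
                       roi = TRUE) {
  design <- experimentDesign(dataset)
  events <- eventTable(dataset)
  pre <- preprocessDataset(dataset)
  values <- boldMatrix(pre)
  regressors <- boldRegressors(events, design)
  partition <- partitionByCondition(events, design, params@nFolds)
  conds <- conditionNames(partition)

  selections <- list()
  repro <- list()
  for (ci in seq_along(conds)) {
    cc <- conds[ci]
    for (f in seq_len(params@nFolds)) {
      sel <- runSelection(values, regressors, partition, cc, f, params,
                          seed = deriveSeed(seed, ci, stage = f))
      selections[[length(selections) + 1L]] <- sel
      vox <- selectedVoxels(sel)
      for (dd in conds) {
        base <- extractPatterns(values, vox, partition, dd, 1L, fold = f)
        for (t in params@tPoints) {
          ps <- extractPatterns(values, vox, partition, dd, t, fold = f)
          R <- reproducibilityIndex(ps, params@reproVariant)
          N <- averageNorm(ps)
          Nd <- averageNorm(differencePatterns(ps, base))
          repro[[length(repro) + 1L]] <- data.frame(
            selection_condition = cc, fold = f, test_condition = dd,
            category = names(R), t = t, R = unname(R), N = unname(N),
            N_diff = unname(Nd), stringsAsFactors = FALSE)
        }
      }
    }
  }
  repro <- do.call(rbind, repro)

  decoding <- decodingGrid(values, selections, partition, t = params@decodeT,
                           cost = params@svmCost)

  roiTab <- NULL
  if (roi) {
    coordsOk <- all(c("x", "y", "z") %in%
                      colnames(SummarizedExperiment::rowData(dataset)))
    if (coordsOk)
      roiTab <- roiAnalysis(values, regressors, partition,
                            voxelCoords(dataset), params@roiSpecs,
                            m = params@roiM, tPoints = params@decodeT,
                            variant = params@reproVariant)
  }

  list(reproducibility = repro, decoding = decoding, roi = roiTab,
       selections = selections, partition = partition)
}

#' Average a subject's grids across cross-validation folds
#'
#' Reduces the per-fold reproducibility rows to the per-subject mean grid
#' (selection condition x test condition x category x t; 32 mean
#' reproducibility indices per time point in the reference design) and the
#' decoding rows to mean accuracy per variant, selection and test condition.
#'
#' @param res result of \code{\link{runSubject}}
#' @return list of data.frames \code{reproducibility} and \code{decoding}
#' @export
averageAcrossFolds <- function(res) {
  r <- res$reproducibility
  rAgg <- stats::aggregate(cbind(R, N, N_diff) ~
                      selection_condition + test_condition + category + t,
                    data = r, FUN = mean)
  d <- res$decoding
  dAgg <- stats::aggregate(accuracy ~ variant + selection_condition + test_condition,
                    data = d, FUN = mean)
  list(reproducibility = rAgg, decoding = dAgg)
}

#' Run a synthetic cohort end to end
#'
#' Generates \code{nSubjects} independent subjects, runs the per-subject
#' pipeline, and aggregates: subject-level mean grids, cross-subject means
#' with SEM, paired Wilcoxon/t contrasts of the reproducibility index
#' between the congruent (and incongruent) condition and the unimodal
#' conditions for every selection condition and category, and per-selection
#' repeated-measures ANOVA with Holm-adjusted pairwise comparisons on the
#' decoding accuracies.
#'
#' @param config a \linkS4class{SyntheticConfig} (its seed seeds the cohort)
#' @param params an \linkS4class{AnalysisParams}
#' @param nSubjects cohort size
#' @param design an \linkS4class{ExperimentDesign}
#' @param statT time point at which group reproducibility contrasts are run
#' @param roi run ROI analyses
#' @return list with \code{subjects} (per-subject mean grids),
#'   \code{reproducibility}, \code{decoding}, \code{roi} (stacked
#'   subject-level tables), \code{means} (cross-subject mean and SEM per
#'   cell), \code{reproTests}, \code{decodingTests}, and \code{balance}
#'   (prediction balance per category)
#' @export
runCohort <- function(config = syntheticConfig(), params = analysisParams(),
                      nSubjects = 9L, design = ExperimentDesign(),
                      statT = 4L, roi = TRUE) {
  if (nSubjects < 2) stop("group statistics need at least 2 subjects")
  datasets <- generateCohort(config, nSubjects, design)
  perSubj <- vector("list", nSubjects)
  reproAll <- list(); decAll <- list(); roiAll <- list()
  for (i in seq_len(nSubjects)) {
    res <- runSubject(datasets[[i]], params,
                      seed = deriveSeed(config@seed, i, stage = 3L),
                      roi = roi)
    agg <- averageAcrossFolds(res)
    agg$reproducibility$subject <- i
    agg$decoding$subject <- i
    perSubj[[i]] <- agg
    reproAll[[i]] <- agg$reproducibility
    decAll[[i]] <- agg$decoding
    if (!is.null(res$roi)) {
      res$roi$subject <- i
      roiAll[[i]] <- res$roi
    }
    balI <- colSums(res$decoding[, c("n_pred_first", "n_pred_second")])
    if (i == 1L) balance <- balI else balance <- balance + balI
  }
  repro <- do.call(rbind, reproAll)
  dec <- do.call(rbind, decAll)
  roiTab <- if (length(roiAll)) do.call(rbind, roiAll) else NULL

  sem <- function(x) sd(x) / sqrt(length(x))
  meansR <- stats::aggregate(R ~ selection_condition + test_condition + category + t,
                      data = repro,
                      FUN = function(x) c(mean = mean(x), sem = sem(x)))
  meansD <- stats::aggregate(accuracy ~ variant + selection_condition +
                        test_condition, data = dec,
                      FUN = function(x) c(mean = mean(x), sem = sem(x)))

  conds <- conditionNames(design)
  contrasts <- rbind(
    data.frame(a = conds[1], b = conds[3]),
    data.frame(a = conds[1], b = conds[4]),
    data.frame(a = conds[2], b = conds[3]),
    data.frame(a = conds[2], b = conds[4]))
  reproTests <- list()
  for (cc in conds) for (g in categoryNames(design)) {
    sub <- repro[repro$selection_condition == cc & repro$category == g &
                   repro$t == statT, ]
    wide <- stats::reshape(sub[, c("subject", "test_condition", "R")],
                           idvar = "subject", timevar = "test_condition",
                           direction = "wide")
    colnames(wide) <- sub("^R\\.", "", colnames(wide))
    for (k in seq_len(nrow(contrasts))) {
      a <- contrasts$a[k]; b <- contrasts$b[k]
      wt <- wilcoxonSignedRank(wide[[a]], wide[[b]])
      tt <- tryCatch(pairedT(wide[[a]], wide[[b]]),
                     error = function(e) list(statistic = NA, df = NA,
                                              p.two.sided = NA,
                                              p.greater = NA, p.less = NA))
      reproTests[[length(reproTests) + 1L]] <- data.frame(
        selection_condition = cc, category = g, t = statT,
        contrast = paste0(a, " > ", b),
        wilcoxon_p_one_sided = wt$p.greater,
        wilcoxon_p_two_sided = wt$p.two.sided,
        t_p_one_sided = tt$p.greater, t_p_two_sided = tt$p.two.sided,
        stringsAsFactors = FALSE)
    }
  }
  reproTests <- do.call(rbind, reproTests)

  decodingTests <- list()
  for (variant in unique(dec$variant)) for (cc in conds) {
    sub <- dec[dec$variant == variant & dec$selection_condition == cc, ]
    wide <- stats::reshape(sub[, c("subject", "test_condition", "accuracy")],
                           idvar = "subject", timevar = "test_condition",
                           direction = "wide")
    mat <- as.matrix(wide[, -1])
    colnames(mat) <- sub("^accuracy\\.", "", colnames(mat))
    an <- rmAnova(mat)
    mc <- multipleComparisons(mat, method = "holm")
    decodingTests[[length(decodingTests) + 1L]] <- list(
      variant = variant, selection_condition = cc,
      F = an$F, df1 = an$df1, df2 = an$df2, p = an$p.value,
      pairwise = mc)
  }

  list(subjects = perSubj, reproducibility = repro, decoding = dec,
       roi = roiTab, meansR = meansR, meansD = meansD,
       reproTests = reproTests, decodingTests = decodingTests,
       balance = balance / sum(balance))
}

#' Write a cohort report to CSV/JSON files
#'
#' @param report result of \code{\link{runCohort}}
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$reproducibility,
            file.path(dir, "reproducibility_by_subject.csv"),
            row.names = FALSE)
  write.csv(report$decoding, file.path(dir, "decoding_by_subject.csv"),
            row.names = FALSE)
  write.csv(report$reproTests, file.path(dir, "reproducibility_tests.csv"),
            row.names = FALSE)
  if (!is.null(report$roi))
    write.csv(report$roi, file.path(dir, "roi_by_subject.csv"),
              row.names = FALSE)
  anova <- do.call(rbind, lapply(report$decodingTests, function(x)
    data.frame(variant = x$variant, selection_condition = x$selection_condition,
               F = x$F, df1 = x$df1, df2 = x$df2, p = x$p)))
  write.csv(anova, file.path(dir, "decoding_anova.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(balance = as.list(report$balance),
           decoding_tests = lapply(report$decodingTests, function(x)
             x[c("variant", "selection_condition", "F", "df1", "df2", "p")])),
      file.path(dir, "group_statistics.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
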