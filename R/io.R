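#' Read and write a data matrix as tab-separated text
#'
#' Plain-text exchange format for the samples x voxels matrix: a header line
#' with voxel ids, then one row per sample; the run of each sample is stored
#' in a leading \code{run} column.
#'
#' @param values samples x voxels matrix with a \code{run} attribute (or
#'   \code{run} argument)
#' @param path file path
#' @param run run id per row
#' @return \code{readDataMatrix}: the matrix with \code{attr(, "run")} set
#' @export
writeDataMatrix <- function(values, path, run = attr(values, "run")) {
  if (is.null(run)) run <- rep(1L, nrow(values))
  df <- data.frame(run = run, values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDataMatrix
#' @export
readDataMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  run <- as.integer(df[[1]])
  out <- as.matrix(df[, -1, drop = FALSE])
  attr(out, "run") <- run
  out
}

#' Export / import a dataset as NIfTI volumes plus BIDS-style sidecars
#'
#' The voxel dimension is serialized along the first image axis (a
#' voxels x 1 x 1 x samples 4D image) together with a companion mask fixing
#' the voxel order, the event table as TSV, and voxel coordinates as CSV.
#' Requires the RNifti package.
#'
#' @param x an \linkS4class{FmriExperiment}
#' @param dir output directory
#' @return \code{importNifti}: the reconstructed samples x voxels matrix with
#'   run attribute, events and coordinates
#' @export
exportNifti <- function(x, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("exportNifti requires the RNifti package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  values <- boldMatrix(x)
  arr <- array(t(values), dim = c(ncol(values), 1L, 1L, nrow(values)))
  RNifti::writeNifti(RNifti::asNifti(arr), file.path(dir, "bold.nii.gz"))
  mask <- array(1L, dim = c(ncol(values), 1L, 1L))
  RNifti::writeNifti(RNifti::asNifti(mask), file.path(dir, "mask.nii.gz"))
  writeEvents(eventTable(x), file.path(dir, "events.tsv"))
  rd <- SummarizedExperiment::rowData(x)
  if (all(c("x", "y", "z") %in% colnames(rd)))
    write.csv(as.data.frame(rd), file.path(dir, "voxels.csv"),
              row.names = FALSE)
  writeLines(as.character(runIds(x)), file.path(dir, "runs.txt"))
  invisible(dir)
}

#' @rdname exportNifti
#' @param dir directory written by \code{exportNifti}
#' @export
importNifti <- function(dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("importNifti requires the RNifti package")
  arr <- RNifti::readNifti(file.path(dir, "bold.nii.gz"))
  mask <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  keep <- which(as.vector(mask) > 0)
  d <- dim(arr)
  flat <- matrix(arr, prod(d[1:3]), d[4])
  values <- t(flat[keep, , drop = FALSE])
  attr(values, "run") <- as.integer(readLines(file.path(dir, "runs.txt")))
  list(values = values,
       events = readEvents(file.path(dir, "events.tsv")),
       voxels = if (file.exists(file.path(dir, "voxels.csv")))
         read.csv(file.path(dir, "voxels.csv")) else NULL)
}
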