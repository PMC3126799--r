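#' @useDynLib sparseMVPA, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL
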