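#' @useDynLib FvModeler, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median runif setNames
#' @importFrom utils data head tail write.csv write.table
#' @import methods
NULL
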