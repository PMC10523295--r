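#' @useDynLib leukoscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head tail read.csv write.csv
NULL
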