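# Namespace imports (roxygen-managed).

#' @importFrom Biostrings pairwiseAlignment
#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
#' @importFrom pracma trapz
#' @importFrom rlang hash
#' @importFrom withr with_seed
#' @importFrom stats dist hclust prcomp predict rgamma rmultinom runif sd setNames
#' @importFrom utils read.table write.table
#' @importFrom graphics matplot
#' @importFrom tools md5sum
NULL
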