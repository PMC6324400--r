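#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

# data.table non-standard evaluation columns
utils::globalVariables(c("value"))
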