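#' @include AllClasses.R
NULL

#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setGeneric("hitGenes", function(x) standardGeneric("hitGenes"))

#' @export
setGeneric("sortFraction", function(x) standardGeneric("sortFraction"))

#' @export
setGeneric("insertions", function(x, population = c("high", "low"))
    standardGeneric("insertions"))

#' @export
setGeneric("screenTruth", function(x) standardGeneric("screenTruth"))

#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))

#' @export
setGeneric("ec50", function(x) standardGeneric("ec50"))
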