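#' @importFrom S4Vectors metadata metadata<-
NULL

#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @export
setGeneric("cellNames", function(x) standardGeneric("cellNames"))

#' @export
setGeneric("mutationNames", function(x) standardGeneric("mutationNames"))

#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setGeneric("nMutations", function(x) standardGeneric("nMutations"))

#' @export
setGeneric("oneState", function(x, j) standardGeneric("oneState"))

#' @export
setGeneric("isLinear", function(x, ...) standardGeneric("isLinear"))

#' @export
setGeneric("flippedMatrix", function(x) standardGeneric("flippedMatrix"))

#' @export
setGeneric("mutationOrder", function(x) standardGeneric("mutationOrder"))

#' @export
setGeneric("objectiveY", function(x) standardGeneric("objectiveY"))

#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @export
setGeneric("fnFlips", function(x) standardGeneric("fnFlips"))

#' @export
setGeneric("fpFlips", function(x) standardGeneric("fpFlips"))

#' @export
setGeneric("imputedPositions", function(x) standardGeneric("imputedPositions"))

#' @export
setGeneric("adPairs", function(x, ...) standardGeneric("adPairs"))

#' @export
setGeneric("adDistance", function(x, y) standardGeneric("adDistance"))

#' @export
setGeneric("cloneGenotypes", function(x) standardGeneric("cloneGenotypes"))

#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' @export
setGeneric("treePattern", function(x) standardGeneric("treePattern"))
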