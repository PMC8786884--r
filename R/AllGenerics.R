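#' @name sampleCorrNet-generics
#' @title Generics for sampleCorrNet classes
#' @description Accessor and analysis generics shared across the package's
#'   S4 classes.
#' @param x,object an object of the relevant class
#' @param ... further arguments passed to methods
#' @keywords internal
NULL

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("peakAreas", function(x) standardGeneric("peakAreas"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("sampleType", function(x) standardGeneric("sampleType"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("corMethod", function(x) standardGeneric("corMethod"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("isolatedNodes", function(x) standardGeneric("isolatedNodes"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("connectedComponents",
    function(x) standardGeneric("connectedComponents"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("voteOutcomes", function(x) standardGeneric("voteOutcomes"))

#' @rdname sampleCorrNet-generics
#' @export
setGeneric("voteThresholds", function(x) standardGeneric("voteThresholds"))
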