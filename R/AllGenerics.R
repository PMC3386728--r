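#' @include AllClasses.R
NULL

#' @export
setGeneric("featureMatrix", function(object, ...) standardGeneric("featureMatrix"))

#' @export
setGeneric("enoseBlock", function(object, ...) standardGeneric("enoseBlock"))

#' @export
setGeneric("acousticBlock", function(object, ...) standardGeneric("acousticBlock"))

#' @export
setGeneric("classLabels", function(object, ...) standardGeneric("classLabels"))

#' @export
setGeneric("blockBoundary", function(object, ...) standardGeneric("blockBoundary"))

#' @export
setGeneric("varianceRatios", function(object, ...) standardGeneric("varianceRatios"))

#' @export
setGeneric("nRetained", function(object, ...) standardGeneric("nRetained"))

#' @export
setGeneric("discriminants", function(object, ...) standardGeneric("discriminants"))

#' @export
setGeneric("classMeans", function(object, ...) standardGeneric("classMeans"))

#' @export
setGeneric("confusionCounts", function(object, ...) standardGeneric("confusionCounts"))

#' @export
setGeneric("accuracy", function(object, ...) standardGeneric("accuracy"))

#' @export
setGeneric("clnnWeights", function(object, ...) standardGeneric("clnnWeights"))

#' @export
setGeneric("clnnBiases", function(object, ...) standardGeneric("clnnBiases"))

#' @export
setGeneric("neuronClassMap", function(object, ...) standardGeneric("neuronClassMap"))

#' @export
setGeneric("quantizationError", function(object, ...) standardGeneric("quantizationError"))

#' @export
setGeneric("discardFirstSniff", function(object, ...) standardGeneric("discardFirstSniff"))
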