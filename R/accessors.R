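#' @include AllClasses.R AllGenerics.R
NULL

#' Extract the samples-by-features matrix
#'
#' @param object a \linkS4class{FeatureSet}.
#' @return numeric matrix, measurements in rows, features in columns.
#' @export
setMethod("featureMatrix", "FeatureSet", function(object) {
  t(assay(object, "features"))
})

#' @describeIn featureMatrix-FeatureSet-method the e-nose feature block.
#' @export
setMethod("enoseBlock", "FeatureSet", function(object) {
  featureMatrix(object)[, seq_len(object@blockBoundary), drop = FALSE]
})

#' @describeIn featureMatrix-FeatureSet-method the acoustic feature block.
#' @export
setMethod("acousticBlock", "FeatureSet", function(object) {
  x <- featureMatrix(object)
  x[, setdiff(seq_len(ncol(x)), seq_len(object@blockBoundary)), drop = FALSE]
})

#' @describeIn featureMatrix-FeatureSet-method the per-sample class factor.
#' @export
setMethod("classLabels", "FeatureSet", function(object) {
  colData(object)$class
})

#' @describeIn featureMatrix-FeatureSet-method number of leading e-nose
#'   features.
#' @export
setMethod("blockBoundary", "FeatureSet", function(object) {
  object@blockBoundary
})

#' @export
setMethod("varianceRatios", "PCAModel", function(object) object@varianceRatios)

#' @export
setMethod("nRetained", "PCAModel", function(object) object@nRetained)

#' @export
setMethod("discriminants", "LDAModel", function(object) object@discriminants)

#' @export
setMethod("classMeans", "LDAModel", function(object) object@classMeans)

#' Confusion counts of a classification report
#'
#' @param object a \linkS4class{ClassificationReport}.
#' @param which \code{"cv"} (leave-one-out) or \code{"original"}
#'   (resubstitution).
#' @return true-class x predicted-class count matrix.
#' @export
setMethod("confusionCounts", "ClassificationReport", function(object,
    which = c("cv", "original")) {
  which <- match.arg(which)
  if (which == "cv") object@cvCounts else object@originalCounts
})

#' Overall percent correctly classified
#'
#' @param object a \linkS4class{ClassificationReport}.
#' @param which \code{"cv"} or \code{"original"}.
#' @return overall percent correct (0--100).
#' @export
setMethod("accuracy", "ClassificationReport", function(object,
    which = c("cv", "original")) {
  m <- confusionCounts(object, which)
  100 * sum(diag(m)) / sum(m)
})

#' @export
setMethod("clnnWeights", "CLNNModel", function(object) object@weights)

#' @export
setMethod("clnnBiases", "CLNNModel", function(object) object@biases)

#' @export
setMethod("neuronClassMap", "CLNNModel", function(object) object@classMap)

#' @export
setMethod("quantizationError", "CLNNModel", function(object)
  object@quantizationError)

# -- show methods ------------------------------------------------------------

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d measurements x %d features (%d e-nose + %d acoustic)\n",
              ncol(object), nrow(object), object@blockBoundary,
              nrow(object) - object@blockBoundary))
  cat("classes:", paste(levels(classLabels(object)), collapse = ", "), "\n")
  sc <- metadata(object)$scaling
  if (length(sc)) cat("scaling records:", length(sc), "\n")
})

setMethod("show", "ClassSpec", function(object) {
  cat(sprintf("ClassSpec %d: week %d, day %d, n = %d (enose sd %.3g, acoustic sd %.3g)\n",
              object@classId, object@harvestWeek, object@day, object@nSamples,
              object@enoseSd, object@acousticSd))
})

setMethod("show", "SniffTrace", function(object) {
  cat(sprintf("SniffTrace (class %d, sniff %d): %d samples x %d channels, baseline [%g, %g)s, draw [%g, %g)s\n",
              object@classId, object@sniffIndex, length(object@time),
              ncol(object@resistance), object@baselineWindow[1],
              object@baselineWindow[2], object@drawWindow[1],
              object@drawWindow[2]))
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components; %d retained at %.0f%% cumulative variance\n",
              length(object@varianceRatios), object@nRetained,
              100 * object@threshold))
  cat("leading ratios:",
      paste(sprintf("%.3f", utils::head(object@varianceRatios, 5)),
            collapse = " "), "\n")
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel: %d classes, %d features, %d discriminants%s\n",
              length(object@classes), ncol(object@classMeans),
              ncol(object@discriminants),
              if (object@ridged) " (ridged within-class scatter)" else ""))
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport (%d classes)\n", length(object@classes)))
  cat(sprintf("  original:        %5.1f%% correct\n",
              accuracy(object, "original")))
  cat(sprintf("  cross-validated: %5.1f%% correct\n", accuracy(object, "cv")))
})

setMethod("show", "CLNNModel", function(object) {
  cat(sprintf("CLNNModel: %d neurons x %d inputs, alpha = %g, bias lr = %g, %d epochs x %d repeats\n",
              nrow(object@weights), ncol(object@weights), object@alpha,
              object@biasLR, object@epochs, object@repeats))
  cat(sprintf("  quantization error: %.4g\n", object@quantizationError))
  if (any(!is.na(object@classMap)))
    cat("  neuron map:", paste(ifelse(is.na(object@classMap), "-",
                                      object@classMap), collapse = " "), "\n")
})
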