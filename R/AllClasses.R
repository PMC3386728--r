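#' aromafuse: e-nose and acoustic sensor fusion for fruit maturity
#'
#' Low-level fusion of electronic-nose smellprints and acoustic firmness
#' indices, with LDA / Wilks'-lambda chemometrics and a competitive learning
#' neural network driven by the discriminant scores. See the package
#' vignette for the modelling background.
#'
#' @name aromafuse-package
#' @aliases aromafuse
#' @import methods
#' @importFrom stats rnorm runif sd prcomp pf predict aggregate median quantile
#' @importFrom utils read.csv write.csv
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
"_PACKAGE"

# -- ClassSpec ---------------------------------------------------------------

#' Per-class specification for the synthetic generator
#'
#' One \code{ClassSpec} describes a single (harvest week, day) group: its
#' mean 32-channel e-nose fractional-response pattern, its mean acoustic
#' firmness pair (FI, AFI), the isotropic noise level of each modality and
#' the number of analysis rows to draw.
#'
#' @slot classId integer class label 1--6.
#' @slot harvestWeek integer, 7 (Green) or 8 (Mature).
#' @slot day integer, days after harvest: 2, 4 or 7.
#' @slot enoseMean numeric(32), mean fractional response per sensor channel.
#' @slot acousticMean numeric(2), mean (FI, AFI).
#' @slot enoseSd non-negative scalar noise sd for the e-nose block.
#' @slot acousticSd non-negative scalar noise sd for the acoustic block.
#' @slot nSamples positive integer, analysis rows for this class.
#'
#' @seealso [defaultClassSpecs()], [validateClassSpecs()]
#' @export
setClass("ClassSpec",
  representation(
    classId = "integer",
    harvestWeek = "integer",
    day = "integer",
    enoseMean = "numeric",
    acousticMean = "numeric",
    enoseSd = "numeric",
    acousticSd = "numeric",
    nSamples = "integer"
  )
)

setValidity("ClassSpec", function(object) {
  msg <- character()
  if (!object@classId %in% 1:6) msg <- c(msg, "classId must be in 1..6")
  if (!object@harvestWeek %in% c(7L, 8L)) msg <- c(msg, "harvestWeek must be 7 or 8")
  if (!object@day %in% c(2L, 4L, 7L)) msg <- c(msg, "day must be 2, 4 or 7")
  if (length(object@enoseMean) != 32L)
    msg <- c(msg, "enoseMean must have 32 channels")
  if (length(object@acousticMean) != 2L)
    msg <- c(msg, "acousticMean must be (FI, AFI)")
  if (length(object@enoseSd) != 1L || is.na(object@enoseSd) || object@enoseSd < 0)
    msg <- c(msg, "enoseSd must be a non-negative scalar")
  if (length(object@acousticSd) != 1L || is.na(object@acousticSd) || object@acousticSd < 0)
    msg <- c(msg, "acousticSd must be a non-negative scalar")
  if (length(object@nSamples) != 1L || is.na(object@nSamples) || object@nSamples < 1L)
    msg <- c(msg, "nSamples must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClassSpec-class Constructor.
#' @param classId,harvestWeek,day,enoseMean,acousticMean,enoseSd,acousticSd,nSamples
#'   see the slot documentation.
#' @export
classSpec <- function(classId, harvestWeek, day, enoseMean, acousticMean,
                      enoseSd = 1, acousticSd = 0.2, nSamples = 80L) {
  new("ClassSpec",
    classId = as.integer(classId), harvestWeek = as.integer(harvestWeek),
    day = as.integer(day), enoseMean = as.numeric(enoseMean),
    acousticMean = as.numeric(acousticMean), enoseSd = as.numeric(enoseSd),
    acousticSd = as.numeric(acousticSd), nSamples = as.integer(nSamples)
  )
}

# -- SniffTrace --------------------------------------------------------------

#' Raw timed 32-channel sniff-cycle recording
#'
#' Holds one sniff cycle: a baseline-purge window (reference gas) followed by
#' a sample-draw window during which the sensors rise towards their
#' steady-state response. All resistances are positive arbitrary units.
#'
#' @slot time numeric, uniformly sampled time points (seconds).
#' @slot resistance numeric matrix, time points x 32 channels, all > 0.
#' @slot baselineWindow numeric(2), half-open baseline window (seconds).
#' @slot drawWindow numeric(2), half-open sample-draw window (seconds).
#' @slot sniffIndex integer >= 1, position of this sniff within the cycle of
#'   repeated sniffs on one fruit.
#' @slot classId integer, class the virtual fruit belongs to.
#'
#' @seealso [generateSniffTrace()], [extractSmax()]
#' @export
setClass("SniffTrace",
  representation(
    time = "numeric",
    resistance = "matrix",
    baselineWindow = "numeric",
    drawWindow = "numeric",
    sniffIndex = "integer",
    classId = "integer"
  )
)

setValidity("SniffTrace", function(object) {
  msg <- character()
  if (nrow(object@resistance) != length(object@time))
    msg <- c(msg, "resistance must have one row per time point")
  if (any(object@resistance <= 0))
    msg <- c(msg, "all resistance values must be positive")
  bw <- object@baselineWindow; dw <- object@drawWindow
  if (length(bw) != 2L || length(dw) != 2L || bw[2] > dw[1])
    msg <- c(msg, "draw window must follow the baseline window")
  inBase <- object@time >= bw[1] & object@time < bw[2]
  inDraw <- object@time >= dw[1] & object@time < dw[2]
  if (sum(inBase) < 2L || sum(inDraw) < 2L)
    msg <- c(msg, "need at least 2 samples in each window")
  if (object@sniffIndex < 1L) msg <- c(msg, "sniffIndex must be >= 1")
  if (length(msg)) msg else TRUE
})

# -- FeatureSet --------------------------------------------------------------

#' Measurements-by-features container with modality blocks
#'
#' A \code{FeatureSet} extends \linkS4class{SummarizedExperiment}: the assay
#' stores features (32 e-nose channels, then FI and AFI) in rows and
#' measurements (sniffs) in columns; \code{colData} carries \code{class},
#' \code{fruit_id} and \code{sniff_index}. The boundary between the e-nose
#' and acoustic feature blocks and any autoscaling records travel in the
#' object so fusion and rescaling remain invertible.
#'
#' @slot blockBoundary integer, number of leading e-nose features; the
#'   remaining features form the acoustic block.
#'
#' @seealso [generateDataset()], [fuseBlocks()], [featureMatrix()]
#' @export
setClass("FeatureSet",
  contains = "SummarizedExperiment",
  representation(blockBoundary = "integer")
)

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (!"class" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'class' column")
  nb <- object@blockBoundary
  if (length(nb) != 1L || is.na(nb) || nb < 0L || nb > nrow(object))
    msg <- c(msg, "blockBoundary must lie within the feature rows")
  if (length(msg)) msg else TRUE
})

#' @describeIn FeatureSet-class Constructor from per-modality sample-by-feature
#'   matrices.
#' @param enose samples x channels matrix of e-nose features.
#' @param acoustic samples x 2 matrix of acoustic features (FI, AFI); may
#'   have zero columns.
#' @param class factor or vector of class labels, one per sample.
#' @param fruitId,sniffIndex optional per-sample identifiers.
#' @param scaling optional list of scaling records stored in
#'   \code{metadata(x)$scaling}.
#' @export
FeatureSet <- function(enose, acoustic = NULL, class, fruitId = NULL,
                       sniffIndex = NULL, scaling = list()) {
  enose <- as.matrix(enose)
  if (is.null(acoustic)) acoustic <- matrix(0, nrow(enose), 0L)
  acoustic <- as.matrix(acoustic)
  stopifnot(nrow(enose) == nrow(acoustic))
  x <- cbind(enose, acoustic)
  if (is.null(colnames(x)))
    colnames(x) <- c(sprintf("ch%02d", seq_len(ncol(enose))),
                     c("FI", "AFI")[seq_len(ncol(acoustic))])
  cd <- DataFrame(class = factor(class))
  if (!is.null(fruitId)) cd$fruit_id <- as.character(fruitId)
  if (!is.null(sniffIndex)) cd$sniff_index <- as.integer(sniffIndex)
  rownames(cd) <- sprintf("s%04d", seq_len(nrow(x)))
  se <- SummarizedExperiment(assays = list(features = t(x)), colData = cd)
  out <- new("FeatureSet", se, blockBoundary = ncol(enose))
  metadata(out)$scaling <- scaling
  out
}

# -- model classes -----------------------------------------------------------

#' Principal component model with a cumulative-variance retention rule
#'
#' @slot loadings orthonormal feature-space loading vectors (columns).
#' @slot varianceRatios fractions of variance explained, non-increasing,
#'   summing to 1.
#' @slot nRetained smallest number of components whose cumulative explained
#'   variance reaches the retention threshold.
#' @slot threshold the cumulative-variance threshold used (default 0.80).
#' @slot center column means removed before rotation.
#'
#' @seealso [pcaFit()], [componentsForVariance()]
#' @export
setClass("PCAModel",
  representation(
    loadings = "matrix",
    varianceRatios = "numeric",
    nRetained = "integer",
    threshold = "numeric",
    center = "numeric"
  )
)

#' Fisher linear discriminant model
#'
#' Discriminant vectors solve the between-/within-class generalized
#' eigenproblem, scaled to unit pooled within-class variance, ordered by
#' decreasing between/within variance ratio. Per-class Fisher linear
#' discriminant functions (equal priors) provide classification; score
#' projections feed the competitive network.
#'
#' @slot classes class labels (factor levels).
#' @slot classMeans classes x features matrix of class centroids.
#' @slot grandMean feature-space grand mean.
#' @slot pooledCov pooled within-class covariance (possibly ridged).
#' @slot discriminants features x d matrix of discriminant vectors,
#'   d <= min(classes - 1, features).
#' @slot eigenvalues between/within variance ratios, non-increasing.
#' @slot funcCoef features x classes Fisher discriminant coefficients.
#' @slot funcConst per-class constants (includes the log prior).
#' @slot priors class prior probabilities (equal by default).
#' @slot ridged TRUE if the within-class scatter needed ridge regularization.
#'
#' @seealso [ldaFit()], [looCrossValidate()]
#' @export
setClass("LDAModel",
  representation(
    classes = "character",
    classMeans = "matrix",
    grandMean = "numeric",
    pooledCov = "matrix",
    discriminants = "matrix",
    eigenvalues = "numeric",
    funcCoef = "matrix",
    funcConst = "numeric",
    priors = "numeric",
    ridged = "logical"
  )
)

#' Resubstitution and cross-validated confusion reports
#'
#' Confusion counts in the layout of a discriminant-analysis classification
#' table: an original (fit-on-all, resubstitution) section and a
#' leave-one-out cross-validated section, each with counts and row
#' percentages.
#'
#' @slot classes class labels.
#' @slot originalCounts true x predicted counts, resubstitution.
#' @slot cvCounts true x predicted counts, leave-one-out.
#'
#' @seealso [looCrossValidate()], [accuracy()], [writeClassificationReport()]
#' @export
setClass("ClassificationReport",
  representation(
    classes = "character",
    originalCounts = "matrix",
    cvCounts = "matrix"
  )
)

setValidity("ClassificationReport", function(object) {
  g <- length(object@classes)
  if (!all(dim(object@originalCounts) == c(g, g)) ||
      !all(dim(object@cvCounts) == c(g, g)))
    return("confusion matrices must be classes x classes")
  TRUE
})

#' Competitive learning network model
#'
#' Winner-take-all layer over LDA discriminant scores: net input is the
#' negative Euclidean distance to each neuron's weight vector plus a
#' conscience bias; the winning neuron's weight moves toward the input by
#' the Kohonen rule.
#'
#' @slot weights neurons x input-dimension weight matrix.
#' @slot biases per-neuron conscience biases.
#' @slot winFreq running win-frequency vector (simplex).
#' @slot alpha Kohonen learning rate in (0, 1].
#' @slot biasLR conscience (bias) learning rate in (0, 1).
#' @slot epochs training epochs per repeat.
#' @slot repeats number of restarts; the lowest-quantization-error repeat is
#'   kept.
#' @slot quantizationError mean distance from training inputs to their
#'   winning neuron's weight.
#' @slot classLevels class labels available to the neuron-to-class map.
#' @slot classMap per-neuron majority class label (NA if the neuron never
#'   wins a mapping sample).
#'
#' @seealso [clnnTrain()], [assignAndMap()], [evaluateSplit()]
#' @export
setClass("CLNNModel",
  representation(
    weights = "matrix",
    biases = "numeric",
    winFreq = "numeric",
    alpha = "numeric",
    biasLR = "numeric",
    epochs = "integer",
    repeats = "integer",
    quantizationError = "numeric",
    classLevels = "character",
    classMap = "character"
  )
)
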