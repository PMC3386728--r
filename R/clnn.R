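#' @include AllClasses.R AllGenerics.R
NULL

#' Net input of a competitive layer
#'
#' The net input of neuron i is the negative Euclidean distance between the
#' input vector and the neuron's weight vector, plus the neuron's bias:
#' \deqn{n_i = -\lVert p - w_i \rVert_2 + b_i.}
#' With zero biases the maximum attainable net input is 0, reached exactly
#' when the input equals a weight vector.
#'
#' @param p input vector (length L).
#' @param w neurons x L weight matrix.
#' @param b per-neuron biases (scalar 0 recycles).
#' @return numeric vector of net inputs, one per neuron.
#' @export
netInput <- function(p, w, b = 0) {
  w <- as.matrix(w)
  if (length(p) != ncol(w))
    stop("input vector and weight rows must have the same dimension")
  unname(b - sqrt(rowSums(sweep(w, 2, p)^2)))
}

#' Winner-take-all competitive transfer function
#'
#' Returns output 1 for the neuron with the highest net input and 0 for all
#' others; exact ties are broken toward the lowest neuron index.
#'
#' @param n net-input vector.
#' @return list with \code{winner} (index) and \code{a} (one-hot output
#'   vector).
#' @export
compete <- function(n) {
  if (!length(n)) stop("empty net input")
  if (any(!is.finite(n))) stop("net input must be finite")
  winner <- as.integer(which.max(n))
  a <- numeric(length(n))
  a[winner] <- 1
  list(winner = winner, a = a)
}

#' Kohonen learning rule
#'
#' Moves the winning neuron's weight vector toward the presented input:
#' \deqn{w' = w + \alpha (p - w),}
#' an exact contraction: \eqn{\lVert w' - p \rVert = (1-\alpha)\lVert w - p \rVert}.
#'
#' @param w current weight vector of the winning neuron.
#' @param p presented input vector.
#' @param alpha learning rate in [0, 1].
#' @return the updated weight vector.
#' @examples
#' kohonenUpdate(c(0.707, 0.707), c(0.196, 0.981), 0.5)
#' @export
kohonenUpdate <- function(w, p, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  w + alpha * (p - w)
}

#' Conscience bias update
#'
#' Maintains a running win-frequency estimate
#' \eqn{c' = (1-\lambda)c + \lambda a} (a is the winner's one-hot vector)
#' and recomputes the biases as
#' \deqn{b_i = e^{1 - \ln c'_i} - e,}
#' so neurons that persistently lose (c decaying toward 0) receive growing
#' biases and re-enter the competition, while a neuron that wins everything
#' (c -> 1) has its bias driven to 0.
#'
#' @param c running win frequencies (on the simplex).
#' @param winner index of the winning neuron.
#' @param lambda bias learning rate in (0, 1); 0 leaves c and b unchanged.
#' @return list with updated \code{c} and \code{b}.
#' @export
biasUpdate <- function(c, winner, lambda) {
  if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
  a <- numeric(length(c))
  a[winner] <- 1
  c2 <- (1 - lambda) * c + lambda * a
  list(c = c2, b = exp(1 - log(c2)) - exp(1))
}

.initWeights <- function(x, neurons, init) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  if (init == "midpoint") {
    matrix(rep((lo + hi) / 2, each = neurons), neurons)
  } else {
    matrix(runif(neurons * ncol(x), rep(lo, each = neurons),
                 rep(hi, each = neurons)), neurons)
  }
}

#' Train a competitive learning network
#'
#' Winner-take-all training over (typically) LDA discriminant scores: per
#' epoch every row is presented once in a freshly shuffled order; the winner
#' of each presentation (and only it) is moved toward the input by the
#' Kohonen rule, and the conscience biases are updated so no neuron dies.
#' Training is restarted \code{repeats} times and the restart with the
#' lowest quantization error (mean distance from each input to its winning
#' neuron's weight) is kept. Fully deterministic under a fixed seed.
#'
#' @param x samples x L input matrix.
#' @param neurons number of competitive neurons S (>= 2, <= rows of x).
#' @param alpha Kohonen learning rate (constant).
#' @param biasLR conscience learning rate lambda.
#' @param epochs presentations of the full data per repeat.
#' @param repeats random restarts; best quantization error wins.
#' @param seed optional integer seed set before training.
#' @param init \code{"midpoint"} starts every neuron at the centre of the
#'   data bounding box (the conscience mechanism then splits them);
#'   \code{"random"} draws each weight uniformly inside the bounding box.
#' @param initWeights explicit S x L initial weight matrix overriding
#'   \code{init} (used e.g. to reproduce the printed worked example).
#' @return a \linkS4class{CLNNModel} (neuron-to-class map unset; see
#'   [assignAndMap()]).
#' @export
clnnTrain <- function(x, neurons = 6L, alpha = 0.1, biasLR = 0.001,
                      epochs = 200L, repeats = 3L, seed = NULL,
                      init = c("midpoint", "random"), initWeights = NULL) {
  x <- as.matrix(x)
  init <- match.arg(init)
  n <- nrow(x)
  S <- as.integer(neurons)
  if (S > n) stop("more neurons than input rows")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(as.integer(repeats))) {
    W <- if (is.null(initWeights)) .initWeights(x, S, init) else
      as.matrix(initWeights)
    stopifnot(nrow(W) == S, ncol(W) == ncol(x))
    cfreq <- rep(1 / S, S)
    b <- exp(1 - log(cfreq)) - exp(1)
    for (e in seq_len(as.integer(epochs))) {
      for (i in sample.int(n)) {
        p <- x[i, ]
        winner <- compete(netInput(p, W, b))$winner
        W[winner, ] <- W[winner, ] + alpha * (p - W[winner, ])
        upd <- biasUpdate(cfreq, winner, biasLR)
        cfreq <- upd$c
        b <- upd$b
      }
    }
    qe <- .quantization(x, W, b)
    if (is.null(best) || qe$qe < best$qe)
      best <- list(W = W, b = b, cfreq = cfreq, qe = qe$qe)
  }
  new("CLNNModel",
      weights = unname(best$W), biases = best$b, winFreq = best$cfreq,
      alpha = alpha, biasLR = biasLR, epochs = as.integer(epochs),
      repeats = as.integer(repeats), quantizationError = best$qe,
      classLevels = character(), classMap = rep(NA_character_, S))
}

# winners for every row (net input with biases) and the mean distance of
# each row to its winner's weight
.quantization <- function(x, W, b) {
  d2 <- outer(rowSums(x^2), rowSums(W^2), `+`) - 2 * x %*% t(W)
  d <- sqrt(pmax(d2, 0))
  net <- sweep(-d, 2, b, `+`)
  winners <- max.col(net, ties.method = "first")
  list(winners = winners, qe = mean(d[cbind(seq_len(nrow(x)), winners)]))
}

#' Assign rows to neurons and map neurons to classes
#'
#' Each row is assigned to its winning neuron; each neuron is then mapped to
#' the majority class among the (training) rows it wins, with ties broken
#' toward the lowest class index. A neuron that wins nothing stays unmapped.
#' The number of distinct classes appearing in the map is the number of
#' classes the unsupervised network actually detected: coincident classes
#' share neurons and are not all recovered.
#'
#' @param model a trained \linkS4class{CLNNModel}.
#' @param x samples x L score matrix (the mapping/training subset).
#' @param labels true class labels of the rows of \code{x}.
#' @return list with \code{model} (map embedded), \code{assignments}
#'   (winning neuron per row), \code{classMap} (per-neuron class or NA) and
#'   \code{nClassesDetected}.
#' @export
assignAndMap <- function(model, x, labels) {
  stopifnot(is(model, "CLNNModel"))
  x <- as.matrix(x)
  labels <- as.factor(labels)
  q <- .quantization(x, model@weights, model@biases)
  S <- nrow(model@weights)
  map <- rep(NA_character_, S)
  for (s in seq_len(S)) {
    members <- labels[q$winners == s]
    if (length(members))
      map[s] <- names(which.max(table(members)))
  }
  model@classLevels <- levels(labels)
  model@classMap <- map
  list(model = model, assignments = q$winners, classMap = map,
       nClassesDetected = length(unique(map[!is.na(map)])))
}

#' Classify new score vectors with a mapped competitive network
#'
#' @param object a \linkS4class{CLNNModel} whose neuron-to-class map has
#'   been set by [assignAndMap()].
#' @param newdata samples x L score matrix.
#' @return factor of predicted classes (NA where the winning neuron is
#'   unmapped).
#' @export
setMethod("predict", "CLNNModel", function(object, newdata) {
  if (all(is.na(object@classMap)))
    stop("model has no neuron-to-class map; run assignAndMap() first")
  q <- .quantization(as.matrix(newdata), object@weights, object@biases)
  factor(object@classMap[q$winners], levels = object@classLevels)
})

#' Train/test evaluation of the LDA-CLNN classifier
#'
#' Stratified split of the data (default 25\% training, 75\% held out); LDA
#' is fitted on the training portion only, the competitive network is
#' trained and mapped on the training rows' leading discriminant scores, and
#' accuracy is measured on the held-out rows -- none of the training rows is
#' used for testing.
#'
#' @param x samples x features matrix (already scaled/fused).
#' @param y class labels.
#' @param trainFrac fraction of each class used for training (default
#'   0.25).
#' @param seed integer seed controlling the split and the network training.
#' @param scoreDims number of leading discriminant scores fed to the
#'   network (default 3).
#' @param neurons,alpha,biasLR,epochs,repeats passed to [clnnTrain()].
#' @return list with \code{trainN}, \code{testN}, \code{nClustersDetected},
#'   \code{accuracy} (percent correct on the held-out rows), \code{confusion}
#'   (held-out true x predicted table), \code{model} and \code{lda}.
#' @export
evaluateSplit <- function(x, y, trainFrac = 0.25, seed = 1, scoreDims = 3L,
                          neurons = 6L, alpha = 0.1, biasLR = 0.001,
                          epochs = 200L, repeats = 3L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  set.seed(as.integer(seed))
  idx <- unlist(lapply(levels(y), function(cl) {
    rows <- which(y == cl)
    sample(rows, round(length(rows) * trainFrac))
  }))
  if (length(unique(y[idx])) < nlevels(y) ||
      length(unique(y[-idx])) < nlevels(y))
    stop("a class is absent from the training or test split")
  lda <- ldaFit(x[idx, , drop = FALSE], y[idx])
  k <- min(scoreDims, ncol(lda@discriminants))
  trainScores <- predict(lda, x[idx, , drop = FALSE], type = "scores")[, seq_len(k), drop = FALSE]
  testScores <- predict(lda, x[-idx, , drop = FALSE], type = "scores")[, seq_len(k), drop = FALSE]
  model <- clnnTrain(trainScores, neurons = neurons, alpha = alpha,
                     biasLR = biasLR, epochs = epochs, repeats = repeats)
  am <- assignAndMap(model, trainScores, y[idx])
  pred <- predict(am$model, testScores)
  truth <- y[-idx]
  acc <- 100 * mean(!is.na(pred) & pred == truth)
  list(trainN = length(idx), testN = nrow(x) - length(idx),
       nClustersDetected = am$nClassesDetected, accuracy = acc,
       confusion = table(truth = truth, predicted = pred, useNA = "ifany"),
       model = am$model, lda = lda)
}
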