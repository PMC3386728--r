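#' @include AllClasses.R AllGenerics.R
NULL

#' Smallest number of components reaching a cumulative-variance threshold
#'
#' @param ratios explained-variance fractions, non-negative and summing
#'   to 1.
#' @param threshold cumulative fraction to reach (default 0.80).
#' @return integer k, the smallest number of leading components whose
#'   cumulative explained variance is at least \code{threshold}.
#' @examples
#' componentsForVariance(c(0.60, 0.25, 0.10, 0.05)) # 2
#' componentsForVariance(rep(0.25, 4))              # 4
#' @export
componentsForVariance <- function(ratios, threshold = 0.8) {
  if (any(ratios < -1e-12) || abs(sum(ratios) - 1) > 1e-6)
    stop("ratios must be non-negative fractions summing to 1")
  as.integer(which(cumsum(ratios) >= threshold - 1e-12)[1])
}

#' Fit a principal component model
#'
#' Exploratory PCA on an (autoscaled) feature matrix. Loadings are the
#' eigenvectors of the sample covariance; the number of retained components
#' is the smallest k whose cumulative explained variance reaches the
#' threshold (80\% by default).
#'
#' @param x samples x features numeric matrix, at least 2 rows.
#' @param threshold cumulative-variance retention threshold.
#' @return a \linkS4class{PCAModel}.
#' @export
pcaFit <- function(x, threshold = 0.8) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows for PCA")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ratios <- fit$sdev^2 / sum(fit$sdev^2)
  new("PCAModel",
      loadings = unname(fit$rotation),
      varianceRatios = ratios,
      nRetained = componentsForVariance(ratios, threshold),
      threshold = threshold,
      center = unname(fit$center))
}

# class means, pooled within-class covariance and Fisher discriminant
# functions; the cheap core shared by ldaFit and each leave-one-out fold.
.ldaCore <- function(x, y, ridgeWarn = TRUE) {
  y <- droplevels(as.factor(y))
  g <- nlevels(y)
  n <- nrow(x)
  p <- ncol(x)
  if (g < 2L) stop("need at least 2 classes")
  if (any(table(y) < 2L)) stop("every class needs at least 2 rows")
  means <- rowsum(x, y) / as.vector(table(y))
  centered <- x - means[y, , drop = FALSE]
  covW <- crossprod(centered) / (n - g)
  ridged <- FALSE
  R <- tryCatch(chol(covW), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < sqrt(.Machine$double.eps) * max(diag(R))) {
    eps <- 1e-8 * sum(diag(covW)) / p
    covW <- covW + diag(eps, p)
    R <- chol(covW)
    ridged <- TRUE
    if (ridgeWarn)
      warning("singular within-class scatter; ridge regularization added")
  }
  covWinv <- chol2inv(R)
  priors <- rep(1 / g, g)
  coef <- covWinv %*% t(means)                       # p x g
  const <- -0.5 * colSums(t(means) * coef) + log(priors)
  list(y = y, classes = levels(y), means = means, covW = covW, chol = R,
       covWinv = covWinv, coef = coef, const = const, priors = priors,
       ridged = ridged, n = n, g = g, p = p)
}

.fisherClassify <- function(core, x) {
  d <- x %*% core$coef
  d <- sweep(d, 2, core$const, `+`)
  # ties broken toward the lowest class index
  factor(core$classes[max.col(d, ties.method = "first")],
         levels = core$classes)
}

#' Fit a Fisher linear discriminant model
#'
#' Computes class means, the pooled within-class covariance (ridge-
#' regularized with a warning if singular), the discriminant vectors that
#' maximize the between- to within-class variance ratio (scaled to unit
#' pooled within-class variance, ordered by decreasing eigenvalue) and the
#' per-class Fisher linear discriminant functions with equal priors.
#'
#' @param x samples x features numeric matrix.
#' @param y class labels (coerced to factor); every class needs >= 2 rows.
#' @return an \linkS4class{LDAModel}.
#' @seealso [predict,LDAModel-method], [looCrossValidate()]
#' @export
ldaFit <- function(x, y) {
  x <- as.matrix(x)
  core <- .ldaCore(x, y)
  d <- min(core$g - 1L, core$p)
  grand <- colMeans(x)
  mc <- sweep(core$means, 2, grand, `-`)
  Sb <- crossprod(mc * sqrt(as.vector(table(core$y))))
  Ri <- backsolve(core$chol, diag(core$p))
  M <- t(Ri) %*% Sb %*% Ri
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  A <- Ri %*% es$vectors[, seq_len(d), drop = FALSE]
  # eigenvalues on the between-/within-scatter scale (Sw^-1 Sb convention)
  evals <- es$values[seq_len(d)] / (core$n - core$g)
  new("LDAModel",
      classes = core$classes,
      classMeans = unname(core$means),
      grandMean = unname(grand),
      pooledCov = core$covW,
      discriminants = unname(A),
      eigenvalues = pmax(evals, 0),
      funcCoef = unname(core$coef),
      funcConst = unname(core$const),
      priors = core$priors,
      ridged = core$ridged)
}

#' Classify or project with an LDA model
#'
#' @param object an \linkS4class{LDAModel}.
#' @param newdata samples x features matrix on the training feature scale.
#' @param type \code{"class"} for Fisher-function classification (ties go to
#'   the lowest class index) or \code{"scores"} for discriminant-score
#'   projections (grand-mean centred, unit pooled within-class variance).
#' @return factor of classes, or a samples x d score matrix.
#' @export
setMethod("predict", "LDAModel", function(object, newdata,
                                          type = c("class", "scores")) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != ncol(object@classMeans))
    stop("newdata must have ", ncol(object@classMeans), " features")
  if (type == "scores")
    return(sweep(x, 2, object@grandMean, `-`) %*% object@discriminants)
  d <- sweep(x %*% object@funcCoef, 2, object@funcConst, `+`)
  factor(object@classes[max.col(d, ties.method = "first")],
         levels = object@classes)
})

#' Leave-one-out cross-validated classification report
#'
#' For each row i the discriminant functions are refitted on all other rows
#' and row i is classified by them; no training row is ever used to test
#' itself. The resubstitution (fit-on-all) confusion is reported alongside.
#' A fold whose removal would leave a class with fewer than 2 members is
#' skipped with a warning.
#'
#' @param x samples x features numeric matrix.
#' @param y class labels.
#' @param screen optional Wilks screening result ([wilksScreen()]); when
#'   supplied, only the kept variables enter the analysis.
#' @return a \linkS4class{ClassificationReport}.
#' @export
looCrossValidate <- function(x, y, screen = NULL) {
  x <- as.matrix(x)
  if (!is.null(screen)) {
    if (!inherits(screen, "data.frame") || is.null(screen$keep))
      stop("screen must be a wilksScreen() result")
    x <- x[, screen$keep, drop = FALSE]
  }
  y <- droplevels(as.factor(y))
  full <- .ldaCore(x, y)
  classes <- full$classes
  g <- length(classes)
  resub <- .fisherClassify(full, x)
  counts <- function(truth, pred) {
    tab <- table(factor(truth, classes), factor(pred, classes))
    matrix(tab, g, g, dimnames = dimnames(tab))
  }
  n <- nrow(x)
  cvPred <- factor(rep(NA_character_, n), levels = classes)
  tooSmall <- table(y) < 3L  # removing one row would leave < 2 members
  for (i in seq_len(n)) {
    if (tooSmall[as.integer(y[i])]) {
      warning("skipping leave-one-out fold ", i,
              ": class would drop below 2 members")
      next
    }
    core <- .ldaCore(x[-i, , drop = FALSE], y[-i], ridgeWarn = FALSE)
    cvPred[i] <- .fisherClassify(core, x[i, , drop = FALSE])
  }
  ok <- !is.na(cvPred)
  new("ClassificationReport",
      classes = classes,
      originalCounts = counts(y, resub),
      cvCounts = counts(y[ok], cvPred[ok]))
}

#' Per-variable Wilks' lambda screening
#'
#' For each variable j the one-way decomposition gives
#' \deqn{\Lambda_j = SS_{within,j} / SS_{total,j},\qquad
#'   F_j = \frac{1 - \Lambda_j}{\Lambda_j}\,\frac{n - g}{g - 1},}
#' the usual one-way ANOVA F statistic. Variables whose F-test p-value
#' exceeds \code{alpha} carry no significant class information and are
#' flagged for dropping.
#'
#' @param x samples x features numeric matrix.
#' @param y class labels.
#' @param alpha significance level of the per-variable F test (default
#'   0.05).
#' @return data.frame with one row per variable: \code{variable},
#'   \code{lambda}, \code{F}, \code{p.value}, \code{keep}.
#' @export
wilksScreen <- function(x, y, alpha = 0.05) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  g <- nlevels(y)
  if (g < 2L) stop("need at least 2 classes")
  means <- rowsum(x, y) / as.vector(table(y))
  ssw <- colSums((x - means[y, , drop = FALSE])^2)
  sst <- colSums(sweep(x, 2, colMeans(x))^2)
  if (any(sst <= 0))
    stop("zero total variance in column(s): ",
         paste(colnames(x)[sst <= 0], collapse = ", "))
  lambda <- ssw / sst
  Fstat <- (1 - lambda) / lambda * (n - g) / (g - 1)
  p <- pf(Fstat, g - 1, n - g, lower.tail = FALSE)
  data.frame(variable = colnames(x) %||% sprintf("V%d", seq_len(ncol(x))),
             lambda = unname(lambda), F = unname(Fstat),
             p.value = unname(p), keep = unname(p <= alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
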