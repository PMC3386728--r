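#' @include AllClasses.R
NULL

# Orthonormal Fourier directions over the 32 channels, used to place class
# means at controlled Euclidean distances (each basis vector has norm 1).
.channelBasis <- function() {
  j <- seq_len(32)
  u1 <- cos(2 * pi * j / 32)
  u2 <- sin(2 * pi * j / 32)
  u3 <- cos(4 * pi * j / 32)
  list(u1 = u1 / sqrt(sum(u1^2)),
       u2 = u2 / sqrt(sum(u2^2)),
       u3 = u3 / sqrt(sum(u3^2)))
}

# Mean FI / AFI per class (index units, on the acousticSd = 1 scale): day-2
# fruit are firm and Green (week 7) firmer than Mature (week 8); by day 4
# and 7 firmness has dropped sharply and the ordering reverses -- the
# qualitative pattern of the published mean firmness table, with day-to-day
# gaps balanced (7-16 sd) so no single contrast dwarfs the others.
.acousticMeans <- function(acousticSd = 1) {
  acousticSd * rbind(
    c(24.0, 23.0),   # week 7 day 2
    c(17.0, 16.0),   # week 7 day 4
    c(10.5, 10.0),   # week 7 day 7
    c(23.0, 22.0),   # week 8 day 2
    c(18.0, 17.0),   # week 8 day 4
    c(11.5, 11.0)    # week 8 day 7
  )
}

#' Study-default class specifications
#'
#' Builds the six \linkS4class{ClassSpec} objects the generator uses by
#' default: classes 1--3 are week-7 (Green) fruit on days 2, 4 and 7, and
#' classes 4--6 are week-8 (Mature) fruit on the same days. The e-nose mean
#' patterns place the three Green classes far apart (pairwise distance
#' \eqn{\ge 7\sigma_e}, reflecting the strong day-to-day volatile changes
#' of immature fruit) while the three Mature classes coincide exactly (the
#' aroma-saturation collapse), with the Mature group as a whole well away
#' from the Green group. The acoustic means follow the qualitative pattern
#' of the published mean firmness table -- firmness falls monotonically
#' with days after harvest, Green firmer than Mature on day 2 and the
#' ordering reversed on days 4 and 7 -- with balanced day-to-day gaps so
#' the six fused class means occupy an essentially three-dimensional
#' subspace and all fifteen pairwise whitened separations stay between
#' about 7 and 23 noise sd. That makes the six groups visible in the first
#' three discriminant scores of the fused data (as in the study) while the
#' e-nose block alone can resolve only four groups.
#'
#' @param enoseSd isotropic per-channel noise sd of the e-nose block
#'   (class-mean offsets scale with it so the separation structure is
#'   preserved).
#' @param acousticSd isotropic noise sd of the acoustic block (acoustic
#'   means scale with it likewise).
#' @param nSamples analysis rows per class.
#' @return list of six validated \linkS4class{ClassSpec} objects.
#' @examples
#' specs <- defaultClassSpecs()
#' specs[[1]]
#' @export
defaultClassSpecs <- function(enoseSd = 1, acousticSd = 1, nSamples = 80L) {
  if (enoseSd <= 0 || acousticSd <= 0)
    stop("noise standard deviations must be positive")
  b <- .channelBasis()
  base <- 6 + 0.6 * cos(6 * pi * seq_len(32) / 32)
  s <- enoseSd
  matureBase <- base + 18 * s * b$u3
  em <- rbind(
    base,                        # wk7 d2
    base + 7 * s * b$u1,         # wk7 d4
    base + 14 * s * b$u1,        # wk7 d7
    matureBase,                  # wk8 d2
    matureBase,                  # wk8 d4
    matureBase                   # wk8 d7
  )
  am <- .acousticMeans(acousticSd)
  weeks <- c(7L, 7L, 7L, 8L, 8L, 8L)
  days <- c(2L, 4L, 7L, 2L, 4L, 7L)
  specs <- lapply(1:6, function(k) {
    classSpec(k, weeks[k], days[k], em[k, ], am[k, ],
              enoseSd = enoseSd, acousticSd = acousticSd,
              nSamples = nSamples)
  })
  validateClassSpecs(specs)
  specs
}

#' Validate the joint separation structure of a class-spec list
#'
#' Checks the dataset-level invariants: exactly six classes, one per
#' (week, day) pair; the three week-8 e-nose means pairwise within
#' \eqn{0.5\sigma_e} (Mature collapse); the three week-7 e-nose means
#' pairwise at least \eqn{6\sigma_e} apart; and every pair of acoustic
#' means whose classes differ in day at least \eqn{6\sigma_a} apart.
#'
#' @param specs list of \linkS4class{ClassSpec}.
#' @return invisibly \code{TRUE}; stops with a descriptive error otherwise.
#' @export
validateClassSpecs <- function(specs) {
  if (length(specs) != 6L)
    stop("a dataset config needs exactly 6 class specs, got ", length(specs))
  lapply(specs, validObject)
  key <- vapply(specs, function(s) paste(s@harvestWeek, s@day), "")
  if (anyDuplicated(key))
    stop("class specs must cover each (week, day) pair exactly once")
  eSd <- vapply(specs, function(s) s@enoseSd, 0)
  aSd <- vapply(specs, function(s) s@acousticSd, 0)
  wk <- vapply(specs, function(s) s@harvestWeek, 0L)
  dy <- vapply(specs, function(s) s@day, 0L)
  em <- do.call(rbind, lapply(specs, function(s) s@enoseMean))
  am <- do.call(rbind, lapply(specs, function(s) s@acousticMean))
  dist2 <- function(m, i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  for (i in 1:5) for (j in (i + 1):6) {
    sdE <- max(eSd[i], eSd[j])
    sdA <- max(aSd[i], aSd[j])
    dE <- dist2(em, i, j)
    if (wk[i] == 8L && wk[j] == 8L && dE > 0.5 * sdE)
      stop(sprintf("week-8 e-nose means %d and %d must collapse (distance %.3g > 0.5 sd)",
                   i, j, dE))
    if (wk[i] == 7L && wk[j] == 7L && dE < 6 * sdE)
      stop(sprintf("week-7 e-nose means %d and %d must separate (distance %.3g < 6 sd)",
                   i, j, dE))
    if (dy[i] != dy[j] && dist2(am, i, j) < 6 * sdA)
      stop(sprintf("acoustic means of classes %d and %d (different days) must be >= 6 sd apart",
                   i, j))
  }
  invisible(TRUE)
}

#' Generate a labelled synthetic feature dataset
#'
#' Draws each analysis row as its class mean plus isotropic Gaussian noise
#' (per modality), reproducing the study layout: six balanced classes, a
#' 32-column e-nose block and a 2-column acoustic block. Rows are organised
#' as repeated sniffs of virtual fruit: \code{nSamples} analysis rows per
#' class correspond to \code{nSamples / (sniffsPerFruit - 1)} fruit whose
#' first sniff has already been discarded (sniff indices start at 2). With
#' \code{includeFirstSniff = TRUE} the discarded first sniffs are also
#' emitted, carrying a residual-gas bias, so the downstream discard rule can
#' be exercised.
#'
#' @param specs list of six \linkS4class{ClassSpec}; defaults to
#'   [defaultClassSpecs()].
#' @param seed integer seed; identical seed and config give identical output.
#' @param sniffsPerFruit sniffs performed per virtual fruit (first one is
#'   the discarded reading).
#' @param includeFirstSniff emit the sniff-index-1 rows as well.
#' @param firstSniffBias additive offset (in units of the e-nose sd) applied
#'   to every channel of a first sniff, emulating residual volatiles.
#' @return a \linkS4class{FeatureSet}; 480 measurements x 34 features for
#'   the default config (600 with first sniffs included).
#' @examples
#' fs <- generateDataset(seed = 1)
#' fs
#' @export
generateDataset <- function(specs = defaultClassSpecs(), seed,
                            sniffsPerFruit = 5L, includeFirstSniff = FALSE,
                            firstSniffBias = 2) {
  validateClassSpecs(specs)
  if (missing(seed)) stop("a seed is required for reproducible generation")
  sniffsPerFruit <- as.integer(sniffsPerFruit)
  if (sniffsPerFruit < 2L) stop("need at least 2 sniffs per fruit")
  set.seed(as.integer(seed))
  keep <- sniffsPerFruit - 1L
  rows <- lapply(specs, function(sp) {
    if (sp@nSamples %% keep != 0L)
      stop(sprintf("nSamples (%d) must be a multiple of sniffsPerFruit - 1 (%d)",
                   sp@nSamples, keep))
    nFruit <- sp@nSamples %/% keep
    sniffIdx <- if (includeFirstSniff) seq_len(sniffsPerFruit) else 1L + seq_len(keep)
    n <- nFruit * length(sniffIdx)
    en <- matrix(rep(sp@enoseMean, each = n), n, 32L) +
      matrix(rnorm(n * 32L, sd = sp@enoseSd), n, 32L)
    ac <- matrix(rep(sp@acousticMean, each = n), n, 2L) +
      matrix(rnorm(n * 2L, sd = sp@acousticSd), n, 2L)
    si <- rep(sniffIdx, times = nFruit)
    if (includeFirstSniff)
      en[si == 1L, ] <- en[si == 1L, , drop = FALSE] + firstSniffBias * sp@enoseSd
    list(enose = en, acoustic = ac,
         class = rep(sp@classId, n),
         fruit = sprintf("c%df%03d", sp@classId, rep(seq_len(nFruit),
                                                     each = length(sniffIdx))),
         sniff = si)
  })
  FeatureSet(
    enose = do.call(rbind, lapply(rows, `[[`, "enose")),
    acoustic = do.call(rbind, lapply(rows, `[[`, "acoustic")),
    class = unlist(lapply(rows, `[[`, "class")),
    fruitId = unlist(lapply(rows, `[[`, "fruit")),
    sniffIndex = unlist(lapply(rows, `[[`, "sniff"))
  )
}

#' Simulate one raw sniff-cycle trace
#'
#' Each channel sits at its baseline resistance during the baseline-purge
#' window and then follows a first-order rise
#' \deqn{R(t) = S_0 (1 + A (1 - e^{-(t - t_d)/\tau}))}
#' through the sample-draw window, where the amplitude vector \eqn{A} is the
#' class's mean fractional-response pattern; with the default
#' \eqn{\tau = 10} s the response reaches over 99\% of its plateau by the
#' end of the 50 s draw, matching steady state within the sniff.
#'
#' @param classId class 1--6 whose mean smellprint sets the amplitudes.
#' @param seed integer seed for the measurement noise.
#' @param specs class specifications; defaults to [defaultClassSpecs()].
#' @param s0 baseline resistance per channel (positive, arbitrary units).
#' @param tau first-order time constant in seconds.
#' @param dt sampling interval in seconds.
#' @param noiseSd multiplicative noise sd relative to baseline (0 = clean).
#' @param sniffIndex sniff position within the repeated cycle.
#' @return a \linkS4class{SniffTrace} with baseline window [0, 10) s and
#'   draw window [10, 60) s.
#' @examples
#' tr <- generateSniffTrace(1, seed = 1)
#' sfrac <- fractionalResponse(extractBaseline(tr), extractSmax(tr))
#' @export
generateSniffTrace <- function(classId, seed, specs = defaultClassSpecs(),
                               s0 = 800 + 20 * (seq_len(32) - 1), tau = 10,
                               dt = 0.5, noiseSd = 0, sniffIndex = 2L) {
  classId <- as.integer(classId)
  if (classId < 1L || classId > length(specs))
    stop("invalid classId: ", classId)
  if (!missing(seed)) set.seed(as.integer(seed))
  A <- specs[[classId]]@enoseMean
  tBase <- c(0, 10); tDraw <- c(10, 60)
  time <- seq(0, tDraw[2] - dt, by = dt)
  rise <- ifelse(time < tDraw[1], 0, 1 - exp(-(time - tDraw[1]) / tau))
  R <- outer(rise, A) # time x channels
  R <- sweep(1 + R, 2, s0, `*`)
  if (noiseSd > 0)
    R <- R + matrix(rnorm(length(R), sd = noiseSd), nrow(R)) *
      rep(s0, each = nrow(R))
  R[R <= 0] <- .Machine$double.eps
  colnames(R) <- sprintf("ch%02d", seq_len(32))
  new("SniffTrace", time = time, resistance = R, baselineWindow = tBase,
      drawWindow = tDraw, sniffIndex = as.integer(sniffIndex),
      classId = classId)
}

#' Printed worked-example fixture for the competitive layer
#'
#' The seven 2-d input vectors, three unit-norm initial weight vectors and
#' the learning rate of the published competitive-layer worked example.
#'
#' @return list with \code{p} (7 x 2 input matrix), \code{w} (3 x 2 initial
#'   weights) and \code{alpha}.
#' @examples
#' fx <- toyClnnFixture()
#' fx$p[2, ]
#' @export
toyClnnFixture <- function() {
  p <- rbind(
    p1 = c(-0.198, 0.974),
    p2 = c(0.196, 0.981),
    p3 = c(0.988, -0.214),
    p4 = c(0.824, -0.512),
    p5 = c(0.524, -0.812),
    p6 = c(-0.351, -0.875),
    p7 = c(-0.725, -0.625)
  )
  w <- rbind(
    w1 = c(0.707, -0.707),
    w2 = c(0.707, 0.707),
    w3 = c(-1.000, 0)
  )
  list(p = p, w = w, alpha = 0.5)
}
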