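#' @include AllClasses.R AllGenerics.R
NULL

#' Fractional (baseline-normalized) sensor response
#'
#' Computes the dimensionless per-channel response
#' \deqn{S_{frac} = (S_{max} - S_0) / S_0,}
#' the standard baseline manipulation that gives each gas sensor a unit
#' response relative to its reference-gas reading and compensates for
#' channels with intrinsically different response levels.
#'
#' @param s0 baseline resistances (reference gas), all strictly positive.
#' @param smax peak resistances during the sample draw, same length.
#' @return numeric vector of fractional responses.
#' @examples
#' fractionalResponse(c(100, 200), c(150, 200))
#' @export
fractionalResponse <- function(s0, smax) {
  if (length(s0) != length(smax))
    stop("s0 and smax must have the same length")
  if (any(!is.finite(s0)) || any(s0 <= 0))
    stop("invalid baseline: all s0 must be finite and > 0")
  (smax - s0) / s0
}

#' Peak draw-window reading per channel
#'
#' @param trace a \linkS4class{SniffTrace}.
#' @return numeric(32), the maximum resistance of each channel within the
#'   sample-draw window.
#' @seealso [extractBaseline()], [traceFractionalResponse()]
#' @export
extractSmax <- function(trace) {
  stopifnot(is(trace, "SniffTrace"))
  dw <- trace@drawWindow
  sel <- trace@time >= dw[1] & trace@time < dw[2]
  if (!any(sel)) stop("empty draw window")
  apply(trace@resistance[sel, , drop = FALSE], 2, max)
}

#' Baseline reading per channel
#'
#' The baseline \eqn{S_0} is taken as the mean resistance over the
#' baseline-purge window, which is robust to sampling noise (as opposed to a
#' single last-sample reading).
#'
#' @param trace a \linkS4class{SniffTrace}.
#' @return numeric(32) baseline resistances.
#' @export
extractBaseline <- function(trace) {
  stopifnot(is(trace, "SniffTrace"))
  bw <- trace@baselineWindow
  sel <- trace@time >= bw[1] & trace@time < bw[2]
  if (!any(sel)) stop("empty baseline window")
  colMeans(trace@resistance[sel, , drop = FALSE])
}

#' Fractional response of a raw trace
#'
#' Convenience composition of [extractBaseline()], [extractSmax()] and
#' [fractionalResponse()].
#'
#' @param trace a \linkS4class{SniffTrace}.
#' @return list with \code{values} (32 fractional responses), \code{s0} and
#'   \code{smax}.
#' @export
traceFractionalResponse <- function(trace) {
  s0 <- extractBaseline(trace)
  smax <- extractSmax(trace)
  list(values = fractionalResponse(s0, smax), s0 = s0, smax = smax)
}

#' Acoustic firmness index
#'
#' The resonance-based stiffness proxy
#' \deqn{FI = M^{2/3} f_0^2 / c,}
#' where \eqn{f_0} is the fruit's dominant resonance frequency after a tap,
#' \eqn{M} its mass and \eqn{c} an instrument scaling factor. The index is
#' homogeneous of degree 2/3 in mass and quadratic in frequency.
#'
#' @param f0 resonance frequency (Hz), positive.
#' @param mass fruit mass (g), positive.
#' @param scaling positive instrument scaling factor; the default 1 is
#'   harmless downstream because all uses follow autoscaling.
#' @return firmness index values.
#' @examples
#' firmnessIndex(2, 8) # 8^(2/3) * 4 = 16
#' @export
firmnessIndex <- function(f0, mass, scaling = 1) {
  if (any(f0 <= 0) || any(mass <= 0) || any(scaling <= 0))
    stop("f0, mass and scaling must all be positive")
  mass^(2 / 3) * f0^2 / scaling
}

#' Average repeated acoustic measurements per fruit
#'
#' Firmness is tapped at several locations around the fruit with repeats at
#' each location; the per-fruit feature is the plain arithmetic mean of FI
#' and of AFI over all location x repeat records.
#'
#' @param records data.frame with columns \code{fruit_id}, \code{FI},
#'   \code{AFI} (optionally \code{location}, \code{repeat_index}).
#' @return data.frame with one row per fruit: \code{fruit_id}, mean
#'   \code{FI}, mean \code{AFI}.
#' @export
averageAcoustic <- function(records) {
  need <- c("fruit_id", "FI", "AFI")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0L) stop("empty acoustic record group")
  out <- aggregate(records[c("FI", "AFI")],
                   by = list(fruit_id = records$fruit_id), FUN = mean)
  out[order(out$fruit_id), , drop = FALSE]
}

#' Drop the first sniff of every fruit
#'
#' The first reading of a sniff cycle is unreliable (residual gases from the
#' previous sample), so all records with \code{sniff_index == 1} are
#' removed. A fruit left with no records, or having only a single sniff to
#' begin with, is dropped entirely with a warning.
#'
#' @param object a data.frame with \code{fruit_id} and \code{sniff_index}
#'   columns, or a \linkS4class{FeatureSet} whose \code{colData} carries
#'   them.
#' @return the filtered object, same type as the input.
#' @export
setMethod("discardFirstSniff", "data.frame", function(object) {
  keep <- .firstSniffKeep(object$fruit_id, object$sniff_index)
  object[keep, , drop = FALSE]
})

#' @rdname discardFirstSniff-data.frame-method
#' @export
setMethod("discardFirstSniff", "FeatureSet", function(object) {
  cd <- colData(object)
  if (!all(c("fruit_id", "sniff_index") %in% colnames(cd)))
    stop("FeatureSet colData must carry fruit_id and sniff_index")
  keep <- .firstSniffKeep(cd$fruit_id, cd$sniff_index)
  object[, keep]
})

.firstSniffKeep <- function(fruit, sniff) {
  if (is.null(fruit) || is.null(sniff))
    stop("fruit_id and sniff_index are required")
  perFruit <- table(fruit)
  lone <- names(perFruit)[perFruit < 2L]
  if (length(lone))
    warning("dropping fruit with a single sniff: ",
            paste(lone, collapse = ", "))
  sniff != 1L & !(fruit %in% lone)
}

#' Autoscale columns to zero mean and unit standard deviation
#'
#' Column-wise standardization (sd with the n - 1 denominator). Columns with
#' zero variance cannot be scaled and are dropped with a warning. When a
#' previously fitted scaling record is supplied the stored statistics are
#' applied instead (e.g. to transform test data with training-set
#' statistics), including the stored column drops.
#'
#' @param x numeric matrix (at least 2 rows when fitting).
#' @param stats optional scaling record (a data.frame as attached by a prior
#'   \code{autoscale} call under \code{attr(, "scaling")}).
#' @return the scaled matrix, with the scaling record in
#'   \code{attr(, "scaling")}: columns \code{column}, \code{center},
#'   \code{scale}, \code{kept}.
#' @examples
#' z <- autoscale(matrix(rnorm(20), 5))
#' round(colMeans(z), 12)
#' @export
autoscale <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  if (is.null(stats)) {
    if (nrow(x) < 2L) stop("need at least 2 rows to fit scaling statistics")
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    kept <- scl > 1e-12 * (1 + abs(ctr))
    if (any(!kept))
      warning("dropping zero-variance column(s): ",
              paste(colnames(x)[!kept], collapse = ", "))
    stats <- data.frame(column = colnames(x), center = ctr, scale = scl,
                        kept = kept, row.names = NULL,
                        stringsAsFactors = FALSE)
  } else {
    stats <- .asScalingRecord(stats)
    if (!identical(stats$column, colnames(x)))
      stop("columns of x do not match the supplied scaling record")
  }
  sel <- which(stats$kept)
  out <- sweep(x[, sel, drop = FALSE], 2, stats$center[sel], `-`)
  out <- sweep(out, 2, stats$scale[sel], `/`)
  attr(out, "scaling") <- stats
  out
}

.asScalingRecord <- function(stats) {
  need <- c("column", "center", "scale", "kept")
  if (!is.data.frame(stats) || !all(need %in% names(stats)))
    stop("a scaling record needs columns: ", paste(need, collapse = ", "))
  stats
}

#' Undo an autoscale transform
#'
#' @param x scaled matrix (kept columns only).
#' @param stats the scaling record produced by [autoscale()].
#' @return matrix on the original scale of the kept columns.
#' @export
unscale <- function(x, stats = attr(x, "scaling")) {
  stats <- .asScalingRecord(stats)
  sel <- which(stats$kept)
  if (ncol(x) != length(sel))
    stop("x must contain exactly the kept columns of the scaling record")
  out <- sweep(as.matrix(x), 2, stats$scale[sel], `*`)
  sweep(out, 2, stats$center[sel], `+`)
}
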