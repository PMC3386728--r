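#' @include preprocessing.R
NULL

#' Low-level fusion of two scaled modality blocks
#'
#' Concatenates the per-modality autoscaled blocks column-wise
#' (\code{[e-nose | acoustic]}) and applies one further autoscale pass over
#' the combined matrix. The second pass is a near-identity when the blocks
#' are already standardized, but guarantees the fused matrix itself has
#' zero-mean, unit-sd columns. Row order and any row names are preserved;
#' the e-nose/acoustic boundary and the final scaling record are attached as
#' attributes so the fusion is invertible.
#'
#' @param enose samples x p1 scaled e-nose block.
#' @param acoustic samples x p2 scaled acoustic block; \code{NULL} or a
#'   zero-column matrix gives a single-modality "fusion" (rescale only).
#' @return fused numeric matrix with attributes \code{blockBoundary} (p1)
#'   and \code{scaling} (the post-fusion record).
#' @examples
#' e <- autoscale(matrix(rnorm(40), 10))
#' a <- autoscale(matrix(rnorm(20), 10))
#' f <- fuseBlocks(e, a)
#' dim(f)
#' @export
fuseBlocks <- function(enose, acoustic = NULL) {
  enose <- as.matrix(enose)
  if (is.null(acoustic)) acoustic <- matrix(0, nrow(enose), 0L)
  acoustic <- as.matrix(acoustic)
  if (nrow(enose) != nrow(acoustic))
    stop("alignment error: modality blocks have different row counts")
  if (!is.null(rownames(enose)) && !is.null(rownames(acoustic)) &&
      !identical(rownames(enose), rownames(acoustic)))
    stop("alignment error: modality blocks have mismatched row keys")
  combined <- cbind(enose, acoustic)
  fused <- autoscale(combined)
  attr(fused, "blockBoundary") <- ncol(enose)
  fused
}

#' Preprocess and fuse a raw FeatureSet
#'
#' Applies the study preprocessing to a raw (unscaled) \linkS4class{FeatureSet}:
#' each modality block is autoscaled separately, then the requested blocks
#' are fused with [fuseBlocks()].
#'
#' @param fs a raw \linkS4class{FeatureSet}.
#' @param modality \code{"fused"} (both blocks), \code{"enose"} or
#'   \code{"acoustic"}.
#' @return the fused samples x features matrix (see [fuseBlocks()]).
#' @export
prepareFeatures <- function(fs, modality = c("fused", "enose", "acoustic")) {
  modality <- match.arg(modality)
  stopifnot(is(fs, "FeatureSet"))
  e <- if (modality %in% c("fused", "enose")) autoscale(enoseBlock(fs)) else NULL
  a <- if (modality %in% c("fused", "acoustic")) autoscale(acousticBlock(fs)) else NULL
  if (is.null(e)) fuseBlocks(a, NULL) else fuseBlocks(e, a)
}
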