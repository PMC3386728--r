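#' @include AllClasses.R
NULL

.featureColumns <- function(nChannels = 32L) {
  c("fruit_id", "class", "sniff_index",
    sprintf("ch%02d", seq_len(nChannels)), "FI", "AFI")
}

#' Write a feature table to CSV
#'
#' One-line header, C decimal point, columns \code{fruit_id, class,
#' sniff_index, ch01..ch32, FI, AFI}.
#'
#' @param fs a \linkS4class{FeatureSet} (32 e-nose + 2 acoustic features).
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeFeatureCsv <- function(fs, path) {
  stopifnot(is(fs, "FeatureSet"))
  cd <- colData(fs)
  x <- featureMatrix(fs)
  df <- data.frame(
    fruit_id = cd$fruit_id %||% sprintf("f%04d", seq_len(nrow(x))),
    class = as.integer(as.character(cd$class)),
    sniff_index = cd$sniff_index %||% rep(2L, nrow(x)),
    x, check.names = FALSE, stringsAsFactors = FALSE
  )
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Validates the header strictly (all 37 expected columns, nothing else read
#' into the features), requires numeric feature cells and rejects duplicate
#' (fruit_id, sniff_index) keys.
#'
#' @param path CSV file written by [writeFeatureCsv()] (or following the
#'   same schema).
#' @return a \linkS4class{FeatureSet}.
#' @export
readFeatureCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expected <- .featureColumns()
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  featCols <- setdiff(expected, c("fruit_id", "class", "sniff_index"))
  feats <- df[featCols]
  bad <- names(feats)[!vapply(feats, is.numeric, TRUE)]
  if (length(bad))
    stop("schema error: non-numeric feature column(s): ",
         paste(bad, collapse = ", "))
  key <- paste(df$fruit_id, df$sniff_index)
  if (anyDuplicated(key))
    stop("duplicate (fruit_id, sniff_index) keys in ", path)
  FeatureSet(
    enose = as.matrix(feats[sprintf("ch%02d", 1:32)]),
    acoustic = as.matrix(feats[c("FI", "AFI")]),
    class = df$class, fruitId = df$fruit_id, sniffIndex = df$sniff_index
  )
}

#' Write a raw sniff trace to CSV
#'
#' Columns \code{time_s, ch01..ch32}.
#'
#' @param trace a \linkS4class{SniffTrace}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "SniffTrace"))
  df <- data.frame(time_s = trace@time, trace@resistance,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a classification report in the two-section confusion layout
#'
#' Emits the resubstitution ("Original") and leave-one-out
#' ("Cross-validated") sections, each with per-class counts and row
#' percentages, as a flat CSV.
#'
#' @param report a \linkS4class{ClassificationReport}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeClassificationReport <- function(report, path) {
  stopifnot(is(report, "ClassificationReport"))
  sect <- function(counts, label) {
    pc <- 100 * counts / rowSums(counts)
    rbind(
      data.frame(section = label, type = "Count",
                 group = report@classes, counts, check.names = FALSE),
      data.frame(section = label, type = "%",
                 group = report@classes, round(pc, 1), check.names = FALSE)
    )
  }
  out <- rbind(sect(report@originalCounts, "Original"),
               sect(report@cvCounts, "Cross-validated"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Wilks' lambda screening table
#'
#' @param wilks result of [wilksScreen()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeWilksTable <- function(wilks, path) {
  write.csv(wilks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
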