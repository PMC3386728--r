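#' @include synthetic-data.R fusion.R chemometrics.R clnn.R io.R
NULL

# FNV-style 31-bit hash of a string; a dependency-free fingerprint for
# config echoing (kept below 2^31 so bitwXor stays in integer range).
.configHash <- function(s) {
  h <- 216613626
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Build a validated experiment configuration
#'
#' Collects every tunable of the end-to-end experiment. Unknown keys are
#' rejected so silent typos cannot change an experiment.
#'
#' @param seed master integer seed; every stage derives its randomness from
#'   it.
#' @param classSpecs list of six \linkS4class{ClassSpec} (default
#'   [defaultClassSpecs()]).
#' @param sniffsPerFruit sniffs per virtual fruit (first discarded).
#' @param includeFirstSniff generate the to-be-discarded first sniffs so the
#'   discard rule runs.
#' @param screeningAlpha Wilks' lambda F-test significance level.
#' @param scoreDims discriminant scores fed to the competitive network.
#' @param neurons,clnnAlpha,biasLR,epochs,repeats competitive network
#'   hyperparameters.
#' @param trainFrac training fraction of the stratified split.
#' @param outputDir optional directory for CSV/JSON outputs.
#' @param ... must be empty; any unknown key is an error.
#' @return a list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(seed = 1L, classSpecs = defaultClassSpecs(),
                             sniffsPerFruit = 5L, includeFirstSniff = TRUE,
                             screeningAlpha = 0.05, scoreDims = 3L,
                             neurons = 6L, clnnAlpha = 0.1, biasLR = 0.001,
                             epochs = 200L, repeats = 3L, trainFrac = 0.25,
                             outputDir = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  cfg <- list(seed = as.integer(seed), classSpecs = classSpecs,
              sniffsPerFruit = as.integer(sniffsPerFruit),
              includeFirstSniff = isTRUE(includeFirstSniff),
              screeningAlpha = screeningAlpha,
              scoreDims = as.integer(scoreDims), neurons = as.integer(neurons),
              clnnAlpha = clnnAlpha, biasLR = biasLR,
              epochs = as.integer(epochs), repeats = as.integer(repeats),
              trainFrac = trainFrac, outputDir = outputDir)
  class(cfg) <- "ExperimentConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.logStage <- function(name, rows, cols, verbose) {
  if (verbose)
    message(sprintf("[%s] rows = %d, cols = %d", name, rows, cols))
}

#' Run the full two-arm fusion experiment
#'
#' Orchestrates generate -> discard first sniffs -> per-modality autoscale ->
#' fuse -> Wilks screening -> PCA -> LDA with leave-one-out cross-validation
#' -> LDA-CLNN split evaluation, for two arms: the e-nose block alone and
#' the fused e-nose + acoustic matrix. The headline of the experiment is the
#' contrast between the arms, so both always run in one invocation.
#'
#' @param config an \code{"ExperimentConfig"} from [experimentConfig()].
#' @param verbose log per-stage row/column counts via [message()].
#' @return list of class \code{"ExperimentResults"}: per-arm results
#'   (\code{wilks}, \code{pca}, \code{lda} report, \code{clnn} evaluation,
#'   \code{nVariables}), a \code{comparison} summary, the echoed
#'   \code{config} and its hash.
#' @export
runExperiment <- function(config = experimentConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  fs <- .stage("generate", generateDataset(
    config$classSpecs, seed = config$seed,
    sniffsPerFruit = config$sniffsPerFruit,
    includeFirstSniff = config$includeFirstSniff))
  .logStage("generate", ncol(fs), nrow(fs), verbose)
  if (config$includeFirstSniff) {
    fs <- .stage("discard-first-sniff", discardFirstSniff(fs))
    .logStage("discard-first-sniff", ncol(fs), nrow(fs), verbose)
  }
  y <- classLabels(fs)
  arms <- list()
  for (arm in c("enose", "fused")) {
    X <- .stage(paste0(arm, "-prepare"),
                prepareFeatures(fs, if (arm == "fused") "fused" else "enose"))
    .logStage(paste0(arm, "-prepare"), nrow(X), ncol(X), verbose)
    nVariables <- ncol(X)
    wil <- .stage(paste0(arm, "-wilks"),
                  wilksScreen(X, y, alpha = config$screeningAlpha))
    Xk <- X[, wil$keep, drop = FALSE]
    .logStage(paste0(arm, "-screened"), nrow(Xk), ncol(Xk), verbose)
    pca <- .stage(paste0(arm, "-pca"), pcaFit(Xk))
    report <- .stage(paste0(arm, "-lda-loo"), looCrossValidate(Xk, y))
    clnn <- .stage(paste0(arm, "-clnn"), evaluateSplit(
      Xk, y, trainFrac = config$trainFrac, seed = config$seed + 1L,
      scoreDims = config$scoreDims, neurons = config$neurons,
      alpha = config$clnnAlpha, biasLR = config$biasLR,
      epochs = config$epochs, repeats = config$repeats))
    arms[[arm]] <- list(nVariables = nVariables, wilks = wil, pca = pca,
                        lda = report, clnn = clnn)
  }
  comparison <- list(
    enose = list(ldaCv = accuracy(arms$enose$lda, "cv"),
                 clnnAccuracy = arms$enose$clnn$accuracy,
                 clustersDetected = arms$enose$clnn$nClustersDetected),
    fused = list(ldaCv = accuracy(arms$fused$lda, "cv"),
                 clnnAccuracy = arms$fused$clnn$accuracy,
                 clustersDetected = arms$fused$clnn$nClustersDetected)
  )
  cfgJson <- jsonlite::toJSON(config[setdiff(names(config), "classSpecs")],
                              auto_unbox = TRUE)
  res <- list(arms = arms, comparison = comparison, config = config,
              configHash = .configHash(as.character(cfgJson)),
              dataset = fs)
  class(res) <- "ExperimentResults"
  if (!is.null(config$outputDir))
    .stage("write-outputs", .writeResults(res, config$outputDir))
  res
}

.writeResults <- function(res, dir) {
  created <- !dir.exists(dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on.exit(if (!is.null(written)) NULL)
  tryCatch({
    for (arm in names(res$arms)) {
      a <- res$arms[[arm]]
      p1 <- file.path(dir, sprintf("%s_lda_report.csv", arm))
      writeClassificationReport(a$lda, p1)
      p2 <- file.path(dir, sprintf("%s_wilks.csv", arm))
      writeWilksTable(a$wilks, p2)
      written <- c(written, p1, p2)
    }
    p3 <- file.path(dir, "features.csv")
    writeFeatureCsv(res$dataset, p3)
    p4 <- file.path(dir, "summary.json")
    jsonlite::write_json(
      list(comparison = res$comparison, configHash = res$configHash,
           seed = res$config$seed,
           config = res$config[setdiff(names(res$config), "classSpecs")]),
      p4, auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, p3, p4)
  }, error = function(e) {
    unlink(written)
    if (created) unlink(dir, recursive = TRUE)
    stop(e)
  })
  invisible(dir)
}

#' @export
print.ExperimentResults <- function(x, ...) {
  cat("Two-arm sensor-fusion experiment (seed", x$config$seed, ")\n")
  for (arm in names(x$comparison)) {
    cm <- x$comparison[[arm]]
    cat(sprintf("  %-6s LDA LOO %5.1f%% | CLNN test %5.1f%% | clusters %d\n",
                arm, cm$ldaCv, cm$clnnAccuracy, cm$clustersDetected))
  }
  invisible(x)
}
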