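# End-to-end pipeline: simulate -> encode -> train -> evaluate -> profile,
# with a manifest recording configuration and seeds for reproducibility.

#' Default pipeline configuration
#'
#' Nested list of stage configurations. Every random operation derives its
#' seed deterministically from the global seed.
#'
#' @param seed global seed.
#' @param width,height sensor geometry.
#' @param nPerClass segments per class.
#' @param windowMs accumulation window (ms).
#' @param epochs training epochs.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L, width = 64, height = 64,
                           nPerClass = 20L, windowMs = 33, epochs = 5L) {
  list(
    seed = as.integer(seed),
    geometry = c(width = width, height = height),
    simulator = list(nPerClass = as.integer(nPerClass), nUsers = 10L,
                     threshold = 0.15, noiseRate = 0.1),
    encoder = list(windowMs = windowMs, dtMicros = 1000),
    training = list(epochs = as.integer(epochs), batchSize = 8L,
                    learningRate = 0.001, rTrue = 0.5, rFalse = 0.03,
                    trainUsers = 1:7, testUsers = 8:10)
  )
}

#' Run the full classification pipeline
#'
#' Simulates a labelled synthetic dataset, writes the event files and label
#' table, trains the spiking classifier on the train-user split, evaluates
#' on the held-out users, profiles complexity on the test traces, and
#' writes a manifest with the configuration, seeds and metrics.
#'
#' @param config configuration list from \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @return list with \code{metrics}, \code{history}, \code{report},
#'   \code{manifest} (invisibly also written to disk).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  gm <- config$geometry
  stageFail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  segs <- tryCatch({
    scene <- sceneModel(width = gm["width"], height = gm["height"])
    generateDataset(scene, kinematicsParams(),
                    emulatorParams(threshold = config$simulator$threshold,
                                   noiseRate = config$simulator$noiseRate),
                    nPerClass = config$simulator$nPerClass,
                    seed = config$seed, nUsers = config$simulator$nUsers)
  }, error = function(e) stageFail("simulate", e))

  dataDir <- file.path(outDir, "dataset")
  dir.create(dataDir, showWarnings = FALSE)
  labels <- data.frame(file = sprintf("segment_%04d.csv", seq_along(segs)),
                       label = vapply(segs, segmentLabel, ""),
                       userId = vapply(segs, userId, 1L),
                       nEvents = vapply(segs, nEvents, 1L))
  for (i in seq_along(segs))
    writeEvents(segmentStream(segs[[i]]), file.path(dataDir, labels$file[i]))
  writeLabels(labels, file.path(dataDir, "labels.csv"))

  tc <- config$training
  split <- splitByUser(segs, tc$trainUsers, tc$testUsers)
  res <- tryCatch({
    net <- buildSpikingConvNet(width = gm["width"], height = gm["height"])
    trainNetwork(net, split$train,
                 trainConfig(epochs = tc$epochs, batchSize = tc$batchSize,
                             learningRate = tc$learningRate,
                             rTrue = tc$rTrue, rFalse = tc$rFalse,
                             seed = config$seed),
                 windowMs = config$encoder$windowMs,
                 dtMicros = config$encoder$dtMicros)
  }, error = function(e) stageFail("train", e))
  saveCheckpoint(res$net, file.path(outDir, "checkpoint.rds"))
  utils::write.csv(res$history, file.path(outDir, "history.csv"),
                   row.names = FALSE)

  metrics <- tryCatch(
    evaluateNetwork(res$net, split$test,
                    windowMs = config$encoder$windowMs,
                    dtMicros = config$encoder$dtMicros),
    error = function(e) stageFail("eval", e))

  report <- tryCatch({
    T <- windowToBins(config$encoder$windowMs, config$encoder$dtMicros)
    enc <- .encodeSegmentsSparse(split$test, config$encoder$dtMicros, T)
    traces <- lapply(enc, function(e)
      forwardPass(res$net, .materialize(e, T))$trace)
    rep <- complexityReport(res$net, traces)
    utils::write.csv(rep@nodes, file.path(outDir, "complexity.csv"),
                     row.names = FALSE)
    rep
  }, error = function(e) stageFail("profile", e))

  manifest <- list(
    config = config,
    configHash = digestConfig(config),
    nSegments = length(segs),
    metrics = metrics[c("accuracy", "precision", "recall", "f1")],
    finalLoss = utils::tail(res$history$loss, 1))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metrics = metrics, history = res$history, report = report,
                 manifest = manifest, outDir = outDir))
}

#' Deterministic configuration hash
#'
#' Serializes the configuration to canonical JSON and applies a polynomial
#' rolling hash, so identical configurations map to identical run
#' identities without an external digest dependency.
#'
#' @param config configuration list.
#' @return hexadecimal hash string.
#' @export
digestConfig <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  mod <- 2147483629
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% mod
  sprintf("%08x", h)
}
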