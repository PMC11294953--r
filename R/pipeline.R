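## Pipeline orchestration: the stages a command-line user chains together
## (simulate -> extract -> select-features -> train -> predict ->
## evaluate), plus runPipeline() which runs them end-to-end on a synthetic
## cohort.  Every artifact embeds the configuration hash and seeds; no
## timestamps, so outputs are byte-reproducible from (inputs, config,
## seed).

#' Default run configuration
#'
#' All pipeline tunables.  Selection and training sizes here are the
#' desk-scale defaults used by \code{\link{runPipeline}}; the module-level
#' defaults of \code{\link{multiSubsetSelect}} (20 subsets, 100
#' iterations) apply when those functions are called directly.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    cohort = list(nPatients = 20L, mutatedFraction = 0.27,
                  volumeShape = c(64L, 64L, 64L)),
    extraction = defaultExtractionConfig(),
    selection = list(nSubsets = 5L, thresholdFraction = 0.5,
                     alpha = 0.05, maxIter = 15L, nTrees = 150L,
                     fallbackK = 10L),
    training = list(classifier = "random_forest", nSubsets = 10L,
                    hyperparams = list(numTrees = 300L, nrounds = 150L,
                                       maxDepth = 4L, eta = 0.1),
                    decisionThreshold = 0.5),
    split = list(testFraction = 0.35))
}

#' Stable short hash of a configuration
#'
#' FNV-1a hash of the canonical JSON serialization; embedded in every run
#' artifact so outputs can be traced to their settings.
#'
#' @param config a configuration list.
#' @return 8-hex-digit character scalar.
#' @export
configHash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

.validateConfig <- function(config) {
  known <- names(defaultRunConfig())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaultRunConfig(), config)
}

.stratifiedSplit <- function(y, testFraction, seed) {
  .withSeed(seed, {
    test <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      nTest <- max(2L, round(length(idx) * testFraction))
      test <- c(test, sample(idx, min(nTest, length(idx) - 2L)))
    }
    list(train = setdiff(seq_along(y), test), test = sort(test))
  })
}

#' Save / load a trained ensemble bundle
#'
#' The bundle directory holds one serialized member per file plus a JSON
#' metadata record (classifier kind, feature list, seeds, threshold).
#'
#' @param model a \linkS4class{BalancedEnsemble}.
#' @param dir bundle directory.
#' @return \code{saveEnsemble} returns \code{dir} invisibly;
#'   \code{loadEnsemble} the restored \linkS4class{BalancedEnsemble}.
#' @export
saveEnsemble <- function(model, dir) {
  stopifnot(is(model, "BalancedEnsemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(classifier = model@classifier,
               featureNames = model@featureNames,
               nSubsets = model@nSubsets,
               decisionThreshold = model@decisionThreshold,
               seeds = model@seeds,
               nMembers = length(model@members))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in seq_along(model@members)) {
    path <- file.path(dir, sprintf("member_%03d", s))
    if (model@classifier == "xgboost")
      xgboost::xgb.save(model@members[[s]], paste0(path, ".ubj"))
    else
      saveRDS(model@members[[s]], paste0(path, ".rds"))
  }
  invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  members <- lapply(seq_len(meta$nMembers), function(s) {
    path <- file.path(dir, sprintf("member_%03d", s))
    if (meta$classifier == "xgboost")
      xgboost::xgb.load(paste0(path, ".ubj"))
    else readRDS(paste0(path, ".rds"))
  })
  new("BalancedEnsemble", members = members,
      classifier = meta$classifier,
      featureNames = meta$featureNames,
      nSubsets = as.integer(meta$nSubsets),
      decisionThreshold = meta$decisionThreshold,
      seeds = as.integer(meta$seeds))
}

#' Run the full pipeline end-to-end on a synthetic cohort
#'
#' simulate -> extract -> select-features -> train -> predict -> evaluate,
#' writing each stage's artifact under \code{outDir}: the cohort NIfTI
#' files and manifest, the feature CSV, a selection JSON, the model
#' bundle, and an evaluation JSON plus a CSV of ROC points.  All stage
#' seeds derive deterministically from \code{masterSeed}, so two runs with
#' the same seed produce byte-identical artifacts.
#'
#' @param outDir output directory.
#' @param masterSeed integer master seed.
#' @param config configuration list (unknown keys are an error); defaults
#'   from \code{\link{defaultRunConfig}}.
#' @param verbose print stage progress.
#' @return invisibly, a list with the evaluation report and artifact
#'   paths.
#' @export
runPipeline <- function(outDir, masterSeed = 1L,
                        config = defaultRunConfig(), verbose = FALSE) {
  config <- .validateConfig(config)
  hash <- configHash(config)
  seeds <- .withSeed(masterSeed, sample.int(2^31 - 1, 4L))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  say("stage simulate")
  cohortDir <- file.path(outDir, "cohort")
  sim <- simulateVolumeCohort(
    nPatients = config$cohort$nPatients,
    mutatedFraction = config$cohort$mutatedFraction,
    volumeShape = config$cohort$volumeShape,
    seed = seeds[1], dir = cohortDir)

  say("stage extract")
  manifest <- readManifest(sim$manifestPath)
  fs <- extractCohortFeatures(manifest, config = config$extraction,
                              verbose = verbose)
  featPath <- file.path(outDir, "features.csv")
  writeFeatureTable(fs, featPath)

  say("stage select-features")
  split <- .stratifiedSplit(idhLabels(fs), config$split$testFraction,
                            seeds[2])
  mat <- featureMatrix(fs)
  y <- idhLabels(fs)
  sel <- suppressWarnings(multiSubsetSelect(
    mat[split$train, , drop = FALSE], y[split$train],
    nSubsets = config$selection$nSubsets,
    thresholdFraction = config$selection$thresholdFraction,
    seed = seeds[3], alpha = config$selection$alpha,
    maxIter = config$selection$maxIter,
    nTrees = config$selection$nTrees,
    fallbackK = config$selection$fallbackK))
  relevant <- relevantFeatures(sel)
  selPath <- file.path(outDir, "selection.json")
  jsonlite::write_json(
    list(configHash = hash, seed = seeds[3],
         nSubsets = sel@nSubsets,
         thresholdFraction = sel@thresholdFraction,
         relevant = relevant,
         frequency = as.list(selectionFraction(sel)[relevant])),
    selPath, auto_unbox = TRUE, digits = NA)

  say("stage train")
  model <- trainEnsemble(
    mat[split$train, relevant, drop = FALSE], y[split$train],
    classifier = config$training$classifier,
    nSubsets = config$training$nSubsets,
    hyperparams = config$training$hyperparams,
    seed = seeds[4],
    decisionThreshold = config$training$decisionThreshold)
  modelDir <- file.path(outDir, "model")
  saveEnsemble(model, modelDir)

  say("stage predict + evaluate")
  probs <- predictProbability(model, mat[split$test, relevant,
                                         drop = FALSE])
  yTest <- y[split$test]
  roc <- suppressWarnings(delongCI(probs, yTest))
  cm <- suppressWarnings(
    classMetrics(as.integer(probs >= model@decisionThreshold), yTest))
  report <- list(configHash = hash, masterSeed = masterSeed,
                 nTrain = length(split$train), nTest = length(split$test),
                 nFeaturesTotal = ncol(mat),
                 nFeaturesSelected = length(relevant),
                 auc = roc@auc, aucSE = roc@aucSE,
                 ci = c(roc@ciLow, roc@ciHigh),
                 metrics = cm[c("accuracy", "sensitivity", "specificity",
                                "precision", "f1")])
  evalPath <- file.path(outDir, "evaluation.json")
  jsonlite::write_json(report, evalPath, auto_unbox = TRUE, digits = NA)
  rocPath <- file.path(outDir, "roc_points.csv")
  data.table::fwrite(data.table::data.table(
    threshold = roc@thresholds, sensitivity = roc@sensitivity,
    fpr = roc@fpr), rocPath)
  invisible(list(report = report,
                 paths = list(manifest = sim$manifestPath,
                              features = featPath, selection = selPath,
                              model = modelDir, evaluation = evalPath,
                              roc = rocPath)))
}
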