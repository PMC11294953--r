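#' @import methods
#' @importFrom stats quantile sd var median rnorm runif setNames pbinom
#'   predict qnorm cov dist
#' @importFrom utils modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib GliomaRadiomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Segmentation label schemes.  FETS and UCSF both use labels {1, 2, 4} but
## with different semantics for labels 1/2; WT_ONLY is a plain binary mask.
.SCHEMES <- c("FETS", "UCSF", "WT_ONLY")
.ROI_KINDS <- c("WT", "NONENH")
.SEQUENCE_TAGS <- c("T1", "T1c", "T2", "FLAIR")

#' Labeled tumor segmentation mask
#'
#' A 3D integer-labeled segmentation of a brain tumor under one of three
#' label schemes: \code{FETS} (1 = necrotic core NCR, 2 = nonenhancing
#' tumor / edema NET/ED, 4 = enhancing tumor ET), \code{UCSF} (1 = NET/NCR,
#' 2 = ED, 4 = ET), or \code{WT_ONLY} (binary whole-tumor mask, labels
#' 0/1).
#'
#' @slot voxels integer 3D array of labels.
#' @slot scheme character scalar, one of \code{"FETS"}, \code{"UCSF"},
#'   \code{"WT_ONLY"}.
#' @export
setClass("LabeledMask",
  representation(voxels = "array", scheme = "character"))

setValidity("LabeledMask", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (!object@scheme %in% .SCHEMES)
    msg <- c(msg, sprintf("scheme must be one of %s",
                          paste(.SCHEMES, collapse = ", ")))
  labs <- unique(as.integer(object@voxels))
  allowed <- if (identical(object@scheme, "WT_ONLY")) c(0L, 1L)
             else c(0L, 1L, 2L, 4L)
  if (!all(labs %in% allowed))
    msg <- c(msg, sprintf(
      "labels outside scheme %s: %s", object@scheme,
      paste(setdiff(labs, allowed), collapse = ", ")))
  if (!any(object@voxels != 0L))
    msg <- c(msg, "segmentation has no nonzero voxel")
  if (length(msg)) msg else TRUE
})

#' Binary region-of-interest mask
#'
#' A binary 3D mask for one of the two tumor regions the framework uses:
#' the whole tumor (\code{WT}, the union of all labels) or the nonenhancing
#' region (\code{NONENH} = NET + NCR + ED, the tumor minus the enhancing
#' component).
#'
#' @slot voxels logical 3D array.
#' @slot roiKind character scalar, \code{"WT"} or \code{"NONENH"}.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @export
setClass("ROIMask",
  representation(voxels = "array", roiKind = "character",
                 spacing = "numeric"))

setValidity("ROIMask", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L || !is.logical(object@voxels))
    msg <- c(msg, "voxels must be a logical 3D array")
  if (!object@roiKind %in% .ROI_KINDS)
    msg <- c(msg, "roiKind must be 'WT' or 'NONENH'")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive reals (mm)")
  if (!any(object@voxels))
    msg <- c(msg, "ROI is empty")
  if (length(msg)) msg else TRUE
})

#' One patient's multicontrast MRI study
#'
#' Holds the four coregistered sequence volumes (T1, postcontrast T1, T2,
#' T2-FLAIR), the voxel spacing, and the labeled tumor segmentation.  All
#' five arrays must share the same shape.
#'
#' @slot patientId character scalar.
#' @slot sequences named list of four numeric 3D arrays, names
#'   \code{T1, T1c, T2, FLAIR}.
#' @slot spacing numeric length-3, voxel spacing in mm, all positive.
#' @slot segmentation a \linkS4class{LabeledMask}.
#' @export
setClass("MRIStudy",
  representation(patientId = "character", sequences = "list",
                 spacing = "numeric", segmentation = "LabeledMask"))

setValidity("MRIStudy", function(object) {
  msg <- character()
  if (!identical(sort(names(object@sequences)), sort(.SEQUENCE_TAGS)))
    msg <- c(msg, sprintf("sequences must be named exactly %s",
                          paste(.SEQUENCE_TAGS, collapse = ", ")))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive reals (mm)")
  shp <- dim(object@segmentation@voxels)
  for (tag in names(object@sequences)) {
    v <- object@sequences[[tag]]
    if (!is.array(v) || length(dim(v)) != 3L)
      msg <- c(msg, sprintf("sequence %s is not a 3D array", tag))
    else if (!identical(dim(v), shp))
      msg <- c(msg, sprintf(
        "sequence %s shape (%s) differs from segmentation shape (%s)",
        tag, paste(dim(v), collapse = ","), paste(shp, collapse = ",")))
    else if (any(!is.finite(v)))
      msg <- c(msg, sprintf("sequence %s contains non-finite voxels", tag))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MRIStudy", function(object) {
  shp <- dim(object@segmentation@voxels)
  cat("MRIStudy '", object@patientId, "'\n", sep = "")
  cat("  sequences: ", paste(names(object@sequences), collapse = ", "),
      "  shape: ", paste(shp, collapse = "x"),
      "  spacing: ", paste(object@spacing, collapse = "x"), " mm\n",
      sep = "")
  cat("  segmentation scheme: ", object@segmentation@scheme,
      "  labels: ",
      paste(sort(unique(as.integer(object@segmentation@voxels))),
            collapse = ","), "\n", sep = "")
})

setMethod("show", "ROIMask", function(object) {
  cat("ROIMask ", object@roiKind, ": ", sum(object@voxels),
      " voxels of ", paste(dim(object@voxels), collapse = "x"),
      " at ", paste(object@spacing, collapse = "x"), " mm\n", sep = "")
})

#' Radiomics feature table
#'
#' Patients-by-features radiomics table stored Bioconductor-style as a
#' \linkS4class{SummarizedExperiment}: features are rows, patients are
#' columns, and the binary IDH label (1 = mutated, 0 = wild type) lives in
#' \code{colData(x)$IDH}.  Feature names follow
#' \code{ROI{1,2}_{sequence}_{imagetype}_{class}_{feature}} with ROI1 = WT
#' and ROI2 = NONENH.
#'
#' @export
setClass("RadiomicsFeatureSet",
  contains = "SummarizedExperiment")

setValidity("RadiomicsFeatureSet", function(object) {
  msg <- character()
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated feature names")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated patient ids")
  if (!"IDH" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain an IDH column")
  else {
    idh <- SummarizedExperiment::colData(object)$IDH
    if (!all(idh %in% c(0L, 1L, NA_integer_)))
      msg <- c(msg, "IDH labels must be 0 (wild type) or 1 (mutated)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RadiomicsFeatureSet", function(object) {
  idh <- SummarizedExperiment::colData(object)$IDH
  cat("RadiomicsFeatureSet: ", nrow(object), " features x ",
      ncol(object), " patients (IDH mutated ", sum(idh == 1, na.rm = TRUE),
      " / wild type ", sum(idh == 0, na.rm = TRUE), ")\n", sep = "")
})

#' Boruta decision for one selection run
#'
#' Per-feature confirmed/rejected/tentative status with accumulated hit
#' counts from the shadow-feature comparison.
#'
#' @slot decisions named character vector, values in
#'   \code{confirmed/rejected/tentative}.
#' @slot hits named integer vector of hit counts.
#' @slot nIterations integer, iterations actually run.
#' @slot alpha numeric significance level.
#' @export
setClass("BorutaDecision",
  representation(decisions = "character", hits = "integer",
                 nIterations = "integer", alpha = "numeric"))

setValidity("BorutaDecision", function(object) {
  msg <- character()
  if (!all(object@decisions %in% c("confirmed", "rejected", "tentative")))
    msg <- c(msg, "invalid decision status")
  if (!identical(names(object@decisions), names(object@hits)))
    msg <- c(msg, "decisions and hits must be aligned by name")
  if (any(object@hits > object@nIterations))
    msg <- c(msg, "hit count exceeds iteration count")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BorutaDecision", function(object) {
  tab <- table(factor(object@decisions,
                      levels = c("confirmed", "tentative", "rejected")))
  cat("BorutaDecision after ", object@nIterations, " iterations (alpha ",
      object@alpha, "): ", tab[["confirmed"]], " confirmed, ",
      tab[["tentative"]], " tentative, ", tab[["rejected"]],
      " rejected\n", sep = "")
})

#' Aggregated selection frequencies across balanced subsets
#'
#' @slot counts named integer vector: number of balanced subsets in which
#'   each feature was confirmed.
#' @slot nSubsets integer.
#' @slot thresholdFraction numeric in (0, 1].
#' @slot fallbackK integer: if no feature reaches the threshold, the top-k
#'   features by frequency are used instead.
#' @export
setClass("SelectionFrequency",
  representation(counts = "integer", nSubsets = "integer",
                 thresholdFraction = "numeric", fallbackK = "integer"))

setValidity("SelectionFrequency", function(object) {
  msg <- character()
  if (any(object@counts > object@nSubsets))
    msg <- c(msg, "counts exceed number of subsets")
  if (object@thresholdFraction <= 0 || object@thresholdFraction > 1)
    msg <- c(msg, "thresholdFraction must be in (0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionFrequency", function(object) {
  rel <- relevantFeatures(object)
  cat("SelectionFrequency over ", object@nSubsets, " balanced subsets: ",
      length(rel), " features at threshold ",
      object@thresholdFraction, "\n", sep = "")
})

#' Balanced-subset classifier ensemble
#'
#' Two-stage model: one classifier fitted per balanced (1:1 undersampled)
#' training subset, combined by arithmetic averaging of the mutated-class
#' probabilities.
#'
#' @slot members list of fitted per-subset classifiers.
#' @slot classifier \code{"random_forest"} or \code{"xgboost"}.
#' @slot featureNames ordered character vector of predictors.
#' @slot nSubsets integer.
#' @slot decisionThreshold numeric, probability cut for class calls.
#' @slot seeds integer vector of per-member seeds.
#' @export
setClass("BalancedEnsemble",
  representation(members = "list", classifier = "character",
                 featureNames = "character", nSubsets = "integer",
                 decisionThreshold = "numeric", seeds = "integer"))

setValidity("BalancedEnsemble", function(object) {
  msg <- character()
  if (!object@classifier %in% c("random_forest", "xgboost"))
    msg <- c(msg, "classifier must be random_forest or xgboost")
  if (length(object@members) < 1L)
    msg <- c(msg, "ensemble has no members")
  if (object@decisionThreshold < 0 || object@decisionThreshold > 1)
    msg <- c(msg, "decisionThreshold must be in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BalancedEnsemble", function(object) {
  cat("BalancedEnsemble: ", length(object@members), " ",
      object@classifier, " members on ", length(object@featureNames),
      " features (threshold ", object@decisionThreshold, ")\n", sep = "")
})
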