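## Whole-study extraction: every (ROI, sequence, image type, class)
## combination, with the fixed naming convention
## ROI{1,2}_{sequence}_{imagetype}_{class}_{feature} (ROI1 = WT,
## ROI2 = NONENH).

.ROI_PREFIX <- c(WT = "ROI1", NONENH = "ROI2")

#' Default extraction settings
#'
#' All tunables of the feature extractor with their defaults: fixed bin
#' width 25 intensity units, coif1 wavelet family, LoG scales 2-5 mm, GLDM
#' similarity tolerance 0.  Degenerate-statistic conventions (constant
#' ROI): GLCM Correlation = 1, entropies = 0, Skewness/Kurtosis = 0,
#' NGTDM Coarseness capped at 1e6.
#'
#' @return named list of settings.
#' @export
defaultExtractionConfig <- function() {
  list(binWidth = 25,
       waveletFamily = "coif1",
       logSigmasMM = c(2, 3, 4, 5),
       gldmAlpha = 0L,
       conventions = list(constantROI = list(
         glcmCorrelation = 1, entropies = 0, skewness = 0, kurtosis = 0,
         ngtdmCoarsenessCap = 1e6)))
}

## one (image, ROI): the 91 intensity features
.extractIntensity <- function(volume, roi, config) {
  fo <- firstOrderFeatures(volume, roi, binWidth = config$binWidth)
  d <- discretizeROI(volume, roi, config$binWidth)
  glcm <- glcmFeatures(d)
  glrlm <- glrlmFeatures(d)
  glszm <- glszmFeatures(d)
  gldm <- gldmFeatures(d, alpha = config$gldmAlpha)
  ngtdm <- ngtdmFeatures(d)
  c(setNames(fo, paste0("firstorder_", names(fo))),
    setNames(glcm, paste0("glcm_", names(glcm))),
    setNames(glrlm, paste0("glrlm_", names(glrlm))),
    setNames(glszm, paste0("glszm_", names(glszm))),
    setNames(gldm, paste0("gldm_", names(gldm))),
    setNames(ngtdm, paste0("ngtdm_", names(ngtdm))))
}

#' Extract the full radiomics feature vector for one study
#'
#' For every constructible ROI and each of the four sequences: 14 shape
#' features on the original image plus the six intensity classes (91
#' features) on the original and all 12 derived images, i.e. 1197 features
#' per (ROI, sequence).  When the segmentation is whole-tumor-only, the
#' NONENH columns are absent and the result carries
#' \code{attr(, "missingROIs")}.
#'
#' @param study an \linkS4class{MRIStudy}.
#' @param roiKinds ROIs to extract, default both.
#' @param config settings list, see \code{\link{defaultExtractionConfig}}.
#' @return named numeric vector; deterministic column order.
#' @export
extractFeatures <- function(study, roiKinds = c("WT", "NONENH"),
                            config = defaultExtractionConfig()) {
  stopifnot(is(study, "MRIStudy"))
  validObject(study)
  missingROIs <- character()
  rois <- list()
  for (rk in roiKinds) {
    roi <- tryCatch(makeROI(study@segmentation, rk, study@spacing),
                    error = function(e) NULL)
    if (is.null(roi)) missingROIs <- c(missingROIs, rk)
    else rois[[rk]] <- roi
  }
  if (length(rois) == 0L)
    stop("no requested ROI is constructible for study ",
         study@patientId, call. = FALSE)
  out <- numeric(0)
  for (tag in .SEQUENCE_TAGS) {
    vol <- study@sequences[[tag]]
    derived <- deriveImages(vol, study@spacing,
                            waveletFamily = config$waveletFamily,
                            logSigmasMM = config$logSigmasMM)
    images <- c(list(original = vol), derived)
    for (rk in names(rois)) {
      roi <- rois[[rk]]
      prefix <- paste(.ROI_PREFIX[[rk]], tag, sep = "_")
      sf <- shapeFeatures(roi)
      out <- c(out, setNames(sf, paste(prefix, "original_shape",
                                       names(sf), sep = "_")))
      for (it in names(images)) {
        fv <- .extractIntensity(images[[it]], roi, config)
        out <- c(out, setNames(fv, paste(prefix, it, names(fv),
                                         sep = "_")))
      }
    }
  }
  ## reorder: ROI-major, then sequence, matching the documented convention
  ord <- order(match(sub("_.*$", "", names(out)), .ROI_PREFIX))
  out <- out[ord]
  if (length(missingROIs)) attr(out, "missingROIs") <- missingROIs
  out
}

#' Extract features for a whole cohort
#'
#' @param manifest data.frame from \code{\link{readManifest}} (or a list of
#'   \linkS4class{MRIStudy} plus an \code{idh} vector).
#' @param roiKinds ROIs to extract.
#' @param config extraction settings.
#' @param verbose print per-patient progress.
#' @return a \linkS4class{RadiomicsFeatureSet}.
#' @export
extractCohortFeatures <- function(manifest, roiKinds = c("WT", "NONENH"),
                                  config = defaultExtractionConfig(),
                                  verbose = FALSE) {
  rows <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    study <- loadStudy(manifest[r, ])
    if (verbose)
      message("extracting ", study@patientId, " (", r, "/",
              nrow(manifest), ")")
    rows[[r]] <- extractFeatures(study, roiKinds = roiKinds,
                                 config = config)
  }
  nm <- unique(unlist(lapply(rows, names)))
  mat <- matrix(NA_real_, nrow(manifest), length(nm),
                dimnames = list(manifest$patient_id, nm))
  for (r in seq_along(rows)) mat[r, names(rows[[r]])] <- rows[[r]]
  RadiomicsFeatureSet(mat, as.integer(manifest$idh))
}
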