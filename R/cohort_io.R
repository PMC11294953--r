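## Cohort I/O: NIfTI volumes, labeled segmentations, manifests and feature
## tables.  Volumes are assumed preprocessed upstream (coregistered, 1 mm
## isotropic, skull-stripped); no resampling happens here and all arrays
## are handled in voxel index space.

#' Construct a LabeledMask
#'
#' @param voxels integer 3D array of segmentation labels.
#' @param scheme label scheme: \code{"FETS"} (1=NCR, 2=NET/ED, 4=ET),
#'   \code{"UCSF"} (1=NET/NCR, 2=ED, 4=ET) or \code{"WT_ONLY"} (0/1).
#' @return a \linkS4class{LabeledMask}.
#' @export
LabeledMask <- function(voxels, scheme = c("FETS", "UCSF", "WT_ONLY")) {
  scheme <- match.arg(scheme)
  storage.mode(voxels) <- "integer"
  new("LabeledMask", voxels = voxels, scheme = scheme)
}

#' Construct an MRIStudy from in-memory arrays
#'
#' @param patientId character scalar.
#' @param sequences named list of numeric 3D arrays with names
#'   \code{T1, T1c, T2, FLAIR}.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param segmentation a \linkS4class{LabeledMask} with the same shape.
#' @return an \linkS4class{MRIStudy}.
#' @export
MRIStudy <- function(patientId, sequences, spacing, segmentation) {
  new("MRIStudy", patientId = as.character(patientId),
      sequences = sequences[.SEQUENCE_TAGS],
      spacing = as.numeric(spacing), segmentation = segmentation)
}

.readNiftiVolume <- function(path) {
  if (!file.exists(path))
    stop("input file does not exist: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1L, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)),
         " dimensions: ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  list(voxels = arr, spacing = as.numeric(spacing))
}

#' Load one patient's study from a manifest row
#'
#' Reads the four sequence volumes and the segmentation named by a manifest
#' row and validates that they form a coherent coregistered study (identical
#' shapes and spacings).
#'
#' @param manifestRow a list or one-row data.frame with elements
#'   \code{patient_id, t1, t1c, t2, flair, seg, scheme}.
#' @return an \linkS4class{MRIStudy}.
#' @export
loadStudy <- function(manifestRow) {
  row <- as.list(manifestRow)
  needed <- c("patient_id", "t1", "t1c", "t2", "flair", "seg", "scheme")
  missing <- setdiff(needed, names(row))
  if (length(missing))
    stop("manifest row lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  paths <- c(T1 = row$t1, T1c = row$t1c, T2 = row$t2, FLAIR = row$flair)
  vols <- lapply(paths, .readNiftiVolume)
  seg <- .readNiftiVolume(row$seg)
  spacing <- vols[[1]]$spacing
  shp <- dim(seg$voxels)
  bad <- character()
  for (tag in names(vols)) {
    if (!identical(dim(vols[[tag]]$voxels), shp))
      bad <- c(bad, sprintf("%s shape (%s) vs segmentation (%s)", tag,
                            paste(dim(vols[[tag]]$voxels), collapse = ","),
                            paste(shp, collapse = ",")))
    if (max(abs(vols[[tag]]$spacing - spacing)) > 1e-6)
      bad <- c(bad, sprintf("%s spacing differs", tag))
  }
  if (length(bad))
    stop("study volumes are not coregistered: ",
         paste(bad, collapse = "; "), call. = FALSE)
  seg.int <- round(seg$voxels)
  MRIStudy(row$patient_id,
           lapply(vols, `[[`, "voxels"),
           spacing,
           LabeledMask(array(as.integer(seg.int), dim = shp),
                       scheme = row$scheme))
}

#' Read a cohort manifest
#'
#' @param path CSV with columns
#'   \code{patient_id, t1, t1c, t2, flair, seg, scheme, idh}.
#' @param relativeTo optional directory the file paths are relative to.
#' @return a data.frame, one row per patient.
#' @export
readManifest <- function(path, relativeTo = NULL) {
  man <- as.data.frame(data.table::fread(path))
  needed <- c("patient_id", "t1", "t1c", "t2", "flair", "seg", "scheme",
              "idh")
  missing <- setdiff(needed, names(man))
  if (length(missing))
    stop("manifest lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.null(relativeTo))
    for (col in c("t1", "t1c", "t2", "flair", "seg"))
      man[[col]] <- file.path(relativeTo, man[[col]])
  man
}

#' Build a binary ROI from a labeled segmentation
#'
#' Two regions of interest are supported: the whole tumor (\code{WT}, union
#' of all nonzero labels) and the nonenhancing region (\code{NONENH} =
#' NET + NCR + ED, i.e. labels 1 and 2 under both the FETS and UCSF
#' schemes).  Binary whole-tumor-only segmentations support only the WT
#' ROI.
#'
#' @param mask a \linkS4class{LabeledMask}.
#' @param roiKind \code{"WT"} or \code{"NONENH"}.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return an \linkS4class{ROIMask}.
#' @export
makeROI <- function(mask, roiKind = c("WT", "NONENH"),
                    spacing = c(1, 1, 1)) {
  stopifnot(is(mask, "LabeledMask"))
  roiKind <- match.arg(roiKind)
  validObject(mask)
  if (identical(mask@scheme, "WT_ONLY") && roiKind == "NONENH")
    stop("NONENH ROI is not available for a whole-tumor-only (WT_ONLY) ",
         "segmentation", call. = FALSE)
  keep <- switch(roiKind,
    WT     = mask@voxels > 0L,
    NONENH = mask@voxels %in% c(1L, 2L))
  vox <- array(keep, dim = dim(mask@voxels))
  if (!any(vox))
    stop("resulting ", roiKind, " ROI is empty", call. = FALSE)
  new("ROIMask", voxels = vox, roiKind = roiKind,
      spacing = as.numeric(spacing))
}

#' Assemble a RadiomicsFeatureSet from a patients-by-features matrix
#'
#' @param mat numeric matrix, patients in rows (rownames = patient ids),
#'   features in columns.
#' @param idh integer vector of labels (1 = mutated, 0 = wild type),
#'   aligned with the rows of \code{mat}.
#' @return a \linkS4class{RadiomicsFeatureSet}.
#' @export
RadiomicsFeatureSet <- function(mat, idh) {
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    stop("feature table is empty", call. = FALSE)
  if (is.null(rownames(mat)))
    stop("feature matrix needs patient ids as rownames", call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicated feature columns: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("duplicated patient rows", call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(mat)),
    colData = S4Vectors::DataFrame(IDH = as.integer(idh),
                                   row.names = rownames(mat)))
  new("RadiomicsFeatureSet", se)
}

#' Write / read a feature table as CSV
#'
#' The CSV layout is patients as rows with a \code{patient_id} column, an
#' \code{IDH} label column, and one column per feature.  Values round-trip
#' losslessly to better than 1e-12 relative tolerance.
#'
#' @param x a \linkS4class{RadiomicsFeatureSet}.
#' @param path output CSV path.
#' @return \code{writeFeatureTable} returns \code{path} invisibly;
#'   \code{readFeatureTable} returns a \linkS4class{RadiomicsFeatureSet}.
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "RadiomicsFeatureSet"))
  mat <- featureMatrix(x)
  dt <- data.table::data.table(patient_id = rownames(mat),
                               IDH = idhLabels(x))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  dt <- data.table::fread(path, check.names = FALSE)
  if (nrow(dt) == 0L)
    stop("feature table is empty: ", path, call. = FALSE)
  nm <- names(dt)
  if (anyDuplicated(nm))
    stop("duplicated columns in feature table: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "),
         call. = FALSE)
  if (!all(c("patient_id", "IDH") %in% nm))
    stop("feature table needs patient_id and IDH columns", call. = FALSE)
  ids <- as.character(dt$patient_id)
  idh <- as.integer(dt$IDH)
  mat <- as.matrix(dt[, setdiff(nm, c("patient_id", "IDH")), with = FALSE])
  rownames(mat) <- ids
  RadiomicsFeatureSet(mat, idh)
}
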