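## Synthetic desk-scale cohorts.  Volume studies emulate the FeTS label
## scheme with a nested-ellipsoid tumor (NCR core, ET shell, ED rim) and
## Gaussian-random-field sequence intensities whose correlation length
## inside the tumor depends on the IDH class, so the class signal is
## carried by texture rather than by first-order mean.

.gaussKernel1D <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  t <- (-r):r
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

## smoothed standard-normal field, standardized to zero mean / unit sd
.grf <- function(shape, corLen) {
  f <- array(rnorm(prod(shape)), dim = shape)
  k <- .gaussKernel1D(corLen)
  for (a in 1:3)
    f <- .convolveAxis(f, .axisMatrix(shape[a], k, "mirror"), a)
  (f - mean(f)) / sd(f)
}

## per-sequence mean offsets per tumor compartment (class-independent, so
## first-order means carry no IDH signal)
.COMPARTMENT_OFFSETS <- list(
  T1    = c(NCR = -25, NETED = -10, ET = 10),
  T1c   = c(NCR = -30, NETED = 0,   ET = 80),
  T2    = c(NCR = 45,  NETED = 30,  ET = 10),
  FLAIR = c(NCR = 10,  NETED = 50,  ET = 25))

#' Simulate a multicontrast MRI cohort
#'
#' Per patient: a nested-ellipsoid tumor labeled with the FeTS scheme
#' (1 = NCR core, 4 = ET shell, 2 = ED rim) inside four sequence volumes
#' built from smoothed Gaussian random fields.  Inside the whole tumor the
#' texture field's correlation length depends on the IDH class
#' (\code{corLenMutated} vs \code{corLenWildtype} voxels); compartment mean
#' offsets are class-independent.  Everything is deterministic given the
#' seed.  When \code{dir} is given, volumes and segmentations are written
#' as NIfTI together with a manifest CSV loadable by
#' \code{\link{readManifest}}.
#'
#' @param nPatients cohort size.
#' @param mutatedFraction prevalence of the mutated class, default 0.27.
#' @param volumeShape array shape, default c(64, 64, 64).
#' @param spacing voxel spacing in mm, default 1 mm isotropic.
#' @param radiiED,radiiET,radiiNCR min/max ellipsoid radius (voxels) per
#'   compartment; ranges must nest (NCR inside ET inside ED).
#' @param corLenMutated,corLenWildtype tumor texture correlation length in
#'   voxels per class.
#' @param textureAmplitude intensity SD of the tumor texture field.
#' @param seed integer seed.
#' @param dir optional output directory for NIfTI files + manifest.
#' @return invisibly, a list with \code{studies} (list of
#'   \linkS4class{MRIStudy}), \code{idh} (integer labels), and
#'   \code{manifest} (data.frame; file paths filled in when \code{dir} is
#'   given).
#' @export
simulateVolumeCohort <- function(nPatients = 20L, mutatedFraction = 0.27,
                                 volumeShape = c(64L, 64L, 64L),
                                 spacing = c(1, 1, 1),
                                 radiiED = c(14, 17),
                                 radiiET = c(9, 12),
                                 radiiNCR = c(4, 6),
                                 corLenMutated = 3,
                                 corLenWildtype = 1.2,
                                 textureAmplitude = 30,
                                 seed = 1L, dir = NULL) {
  if (mutatedFraction <= 0 || mutatedFraction >= 1)
    stop("mutatedFraction must be strictly between 0 and 1",
         call. = FALSE)
  if (!(max(radiiNCR) < min(radiiET) && max(radiiET) < min(radiiED)))
    stop("compartment radius ranges must nest: NCR < ET < ED",
         call. = FALSE)
  if (min(radiiED) * 2 + 6 > min(volumeShape))
    stop("volume too small for the requested tumor radii", call. = FALSE)
  nMut <- max(1L, round(nPatients * mutatedFraction))
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  studies <- vector("list", nPatients)
  manifest <- NULL
  idh <- integer(nPatients)
  .withSeed(seed, {
    labels <- sample(c(rep(1L, nMut), rep(0L, nPatients - nMut)))
    ax <- seq_len(volumeShape[1])
    ay <- seq_len(volumeShape[2])
    az <- seq_len(volumeShape[3])
    for (pt in seq_len(nPatients)) {
      idh[pt] <- labels[pt]
      ctr <- volumeShape / 2 + runif(3, -2, 2)
      aniso <- runif(3, 0.9, 1.1)
      rED <- runif(1, radiiED[1], radiiED[2]) * aniso
      rET <- runif(1, radiiET[1], radiiET[2]) * aniso
      rNCR <- runif(1, radiiNCR[1], radiiNCR[2]) * aniso
      insideR <- function(r) {
        dx2 <- ((ax - ctr[1]) / r[1])^2
        dy2 <- ((ay - ctr[2]) / r[2])^2
        dz2 <- ((az - ctr[3]) / r[3])^2
        outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
      }
      inED <- insideR(rED); inET <- insideR(rET); inNCR <- insideR(rNCR)
      seg <- array(0L, volumeShape)
      seg[inED] <- 2L
      seg[inET] <- 4L
      seg[inNCR] <- 1L
      corLen <- if (labels[pt] == 1L) corLenMutated else corLenWildtype
      seqs <- list()
      for (tag in .SEQUENCE_TAGS) {
        vol <- 100 + 20 * .grf(volumeShape, 2)
        off <- .COMPARTMENT_OFFSETS[[tag]]
        vol[seg == 1L] <- vol[seg == 1L] + off[["NCR"]]
        vol[seg == 2L] <- vol[seg == 2L] + off[["NETED"]]
        vol[seg == 4L] <- vol[seg == 4L] + off[["ET"]]
        texture <- .grf(volumeShape, corLen)
        vol[inED] <- vol[inED] + textureAmplitude * texture[inED]
        seqs[[tag]] <- pmax(vol, 0)
      }
      pid <- sprintf("SYN%03d", pt)
      studies[[pt]] <- MRIStudy(pid, seqs, spacing,
                                LabeledMask(seg, "FETS"))
    }
  })
  files <- data.frame(patient_id = vapply(studies, slot, "",
                                          "patientId"),
                      t1 = "", t1c = "", t2 = "", flair = "", seg = "",
                      scheme = "FETS", idh = idh,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    for (pt in seq_len(nPatients)) {
      pid <- files$patient_id[pt]
      paths <- file.path(dir, paste0(
        pid, "_", c("t1", "t1c", "t2", "flair", "seg"), ".nii.gz"))
      vols <- c(studies[[pt]]@sequences,
                list(array(as.numeric(studies[[pt]]@segmentation@voxels),
                           dim = volumeShape)))
      for (q in 1:5)
        RNifti::writeNifti(RNifti::asNifti(vols[[q]], pixdim = spacing),
                           paths[q])
      files[pt, c("t1", "t1c", "t2", "flair", "seg")] <- paths
    }
    data.table::fwrite(files, file.path(dir, "manifest.csv"))
  }
  invisible(list(studies = studies, idh = idh, manifest = files,
                 manifestPath = if (!is.null(dir))
                   file.path(dir, "manifest.csv") else NULL))
}

#' Simulate a tabular imbalanced feature cohort
#'
#' Informative features get a class-conditional Gaussian mean shift of
#' \code{effectSize} standard deviations; the remaining features are pure
#' standard-normal noise.  Class counts follow the imbalance ratio
#' (majority:minority), deterministic per seed.
#'
#' @param n samples.
#' @param p features.
#' @param nInformative number of informative features (the first columns).
#' @param effectSize mean shift in SD units.
#' @param imbalanceRatio majority:minority ratio (>= 1).
#' @param seed integer seed.
#' @return list with matrix \code{X} (colnames \code{F001...}), labels
#'   \code{y} (1 = minority/mutated), and \code{informative} (names of the
#'   planted features).
#' @export
simulateTabularCohort <- function(n, p, nInformative = 0L,
                                  effectSize = 0, imbalanceRatio = 1,
                                  seed = 1L) {
  if (nInformative > p)
    stop("nInformative must not exceed p", call. = FALSE)
  if (imbalanceRatio < 1)
    stop("imbalanceRatio must be >= 1", call. = FALSE)
  nPos <- round(n / (imbalanceRatio + 1))
  if (nPos < 2L || n - nPos < 2L)
    stop("both classes need at least two samples", call. = FALSE)
  .withSeed(seed, {
    y <- sample(c(rep(1L, nPos), rep(0L, n - nPos)))
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("F%03d", seq_len(p))))
    if (nInformative > 0L)
      X[y == 1L, seq_len(nInformative)] <-
        X[y == 1L, seq_len(nInformative)] + effectSize
    list(X = X, y = y,
         informative = colnames(X)[seq_len(nInformative)])
  })
}
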