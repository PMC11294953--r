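## Radiomics feature extraction.  Seven feature classes: 14 shape (ROI
## geometry, original image only), and six intensity classes computed on
## the original plus all 12 derived images: 18 first-order, 22 GLCM,
## 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM.  Total per (ROI, sequence):
## 14 + 91 * 13 = 1197.

FEATURE_CLASS_SIZES <- c(shape = 14L, firstorder = 18L, glcm = 22L,
                         glrlm = 16L, glszm = 16L, gldm = 14L, ngtdm = 5L)

#' Discretized ROI
#'
#' Fixed-bin-width gray-level discretization of the in-ROI intensities,
#' anchored at the ROI minimum: \code{level(x) = floor((x - min)/w) + 1}.
#'
#' @slot levels integer 3D array cropped to the ROI bounding box; 0 marks
#'   voxels outside the ROI.
#' @slot nLevels integer number of gray levels.
#' @slot binWidth positive real, intensity units.
#' @slot binEdges numeric vector of bin edges.
#' @export
setClass("DiscretizedROI",
  representation(levels = "array", nLevels = "integer",
                 binWidth = "numeric", binEdges = "numeric"))

setMethod("show", "DiscretizedROI", function(object) {
  cat("DiscretizedROI: ", sum(object@levels > 0L), " voxels, ",
      object@nLevels, " gray levels (bin width ", object@binWidth,
      ")\n", sep = "")
})

.cropToROI <- function(volume, mask) {
  stopifnot(identical(dim(volume), dim(mask)))
  idx <- which(mask, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  list(volume = volume[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                       rng[1, 3]:rng[2, 3], drop = FALSE],
       mask = mask[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                   rng[1, 3]:rng[2, 3], drop = FALSE])
}

#' Discretize in-ROI intensities with a fixed bin width
#'
#' @param volume numeric 3D array.
#' @param roi an \linkS4class{ROIMask} (or logical array of same shape).
#' @param binWidth positive bin width in intensity units (default 25).
#' @return a \linkS4class{DiscretizedROI}.
#' @export
discretizeROI <- function(volume, roi, binWidth = 25) {
  if (binWidth <= 0) stop("binWidth must be positive", call. = FALSE)
  mask <- if (is(roi, "ROIMask")) roi@voxels else roi
  if (!any(mask)) stop("ROI is empty", call. = FALSE)
  cr <- .cropToROI(volume, mask)
  vals <- cr$volume[cr$mask]
  lo <- min(vals)
  lev <- as.integer(floor((vals - lo) / binWidth)) + 1L
  nl <- max(lev)
  levels <- array(0L, dim = dim(cr$mask))
  levels[cr$mask] <- lev
  new("DiscretizedROI", levels = levels, nLevels = nl,
      binWidth = binWidth,
      binEdges = lo + binWidth * seq(0L, nl))
}

#' First-order intensity statistics (18 features)
#'
#' Energy, TotalEnergy, Entropy, Minimum, 10Percentile, 90Percentile,
#' Maximum, Mean, Median, InterquartileRange, Range, MeanAbsoluteDeviation,
#' RobustMeanAbsoluteDeviation, RootMeanSquared, Skewness, Kurtosis
#' (non-excess), Variance (population), Uniformity.  Entropy and Uniformity
#' are computed on the fixed-bin-width discretized histogram.  On a
#' constant ROI, Skewness and Kurtosis are 0 by convention.
#'
#' @param volume numeric 3D array.
#' @param roi an \linkS4class{ROIMask} or logical array.
#' @param binWidth bin width for the histogram-based features.
#' @param spacing voxel spacing in mm (for TotalEnergy); taken from the
#'   ROI when available.
#' @return named numeric vector of length 18.
#' @export
firstOrderFeatures <- function(volume, roi, binWidth = 25,
                               spacing = NULL) {
  mask <- if (is(roi, "ROIMask")) roi@voxels else roi
  if (is.null(spacing))
    spacing <- if (is(roi, "ROIMask")) roi@spacing else c(1, 1, 1)
  x <- volume[mask]
  n <- length(x)
  if (n == 0L) stop("ROI is empty", call. = FALSE)
  d <- discretizeROI(volume, mask, binWidth)
  pHist <- tabulate(d@levels[d@levels > 0L], nbins = d@nLevels) / n
  pHist <- pHist[pHist > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                type = 7)
  inner <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2),
    TotalEnergy = prod(spacing) * sum(x^2),
    Entropy = -sum(pHist * log2(pHist)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pHist^2))
}

#' 3D shape features (14 features)
#'
#' Surface area and mesh volume come from a triangulated isosurface of the
#' binary mask (marching tetrahedra at iso level 0.5 on the zero-padded
#' grid); axis lengths from the principal moments of the physical voxel
#' coordinates; diameters from boundary-voxel coordinates.
#'
#' @param roi an \linkS4class{ROIMask}.
#' @return named numeric vector of length 14.
#' @export
shapeFeatures <- function(roi) {
  stopifnot(is(roi, "ROIMask"))
  cr <- .cropToROI(roi@voxels, roi@voxels)
  mask <- cr$mask
  spacing <- roi@spacing
  if (any(dim(mask) == 1L))
    warning("ROI is a single voxel thick along some axis; mesh features ",
            "are computed on the zero-padded mask")
  ## anti-aliased isosurface: mesh the mildly smoothed indicator field
  ## (sigma 0.8 voxels) at level 0.5 to remove the staircase bias of a
  ## binary marching mesh
  pad <- 3L
  pd <- dim(mask) + 2L * pad
  field <- array(0, pd)
  field[pad + seq_len(dim(mask)[1]), pad + seq_len(dim(mask)[2]),
        pad + seq_len(dim(mask)[3])] <- as.numeric(mask)
  sm <- field
  kern <- .gaussKernel1D(0.8)
  for (a in 1:3)
    sm <- .convolveAxis(sm, .axisMatrix(pd[a], kern, "mirror"), a)
  if (max(sm) <= 0.5) {
    warning("ROI too small for the anti-aliased surface mesh; ",
            "falling back to the binary-mask mesh")
    sm <- field
  }
  mesh <- .cppMarchingMesh(sm, pd, as.numeric(spacing), 0.5)
  area <- mesh[1]; meshVol <- mesh[2]
  nvox <- sum(mask)
  voxVol <- nvox * prod(spacing)
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx, 2, spacing, `*`)
  ## boundary voxels: any 6-neighbor missing (or at the crop edge)
  shifted <- function(di, dj, dk) {
    out <- array(FALSE, dim(mask) + 2L)
    out[2:(dim(mask)[1] + 1) + di, 2:(dim(mask)[2] + 1) + dj,
        2:(dim(mask)[3] + 1) + dk] <- mask
    out[2:(dim(mask)[1] + 1), 2:(dim(mask)[2] + 1),
        2:(dim(mask)[3] + 1), drop = FALSE]
  }
  interior <- shifted(1L, 0L, 0L) & shifted(-1L, 0L, 0L) &
              shifted(0L, 1L, 0L) & shifted(0L, -1L, 0L) &
              shifted(0L, 0L, 1L) & shifted(0L, 0L, -1L)
  bmask <- mask & !interior
  bidx <- which(bmask, arr.ind = TRUE)
  bcoords <- sweep(bidx, 2, spacing, `*`)
  max3d <- .cppMaxDist(bcoords)
  maxPlane <- function(fixAxis) {
    planes <- unique(bidx[, fixAxis])
    best <- 0
    for (pl in planes) {
      sel <- bidx[, fixAxis] == pl
      if (sum(sel) < 2L) next
      best <- max(best, .cppMaxDist(bcoords[sel, -fixAxis, drop = FALSE]))
    }
    best
  }
  ## principal axes from the coordinate covariance
  if (nrow(coords) > 1L) {
    ev <- sort(pmax(eigen(stats::cov(coords), symmetric = TRUE,
                          only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  least <- 4 * sqrt(ev[3])
  c(MeshVolume = meshVol,
    VoxelVolume = voxVol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / meshVol,
    Sphericity = pi^(1 / 3) * (6 * meshVol)^(2 / 3) / area,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = maxPlane(3L),
    Maximum2DDiameterColumn = maxPlane(2L),
    Maximum2DDiameterRow = maxPlane(1L),
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gray-level co-occurrence matrix features (22 features)
#'
#' Co-occurrence is counted over the 13 unique 3D direction offsets at
#' distance 1, symmetrized and normalized per direction; each feature is
#' computed per direction and averaged over directions.  On a single-level
#' ROI, Correlation is 1 and entropies 0 by convention.
#'
#' @param d a \linkS4class{DiscretizedROI}.
#' @return named numeric vector of length 22.
#' @export
glcmFeatures <- function(d) {
  ng <- d@nLevels
  counts <- .cppGLCM(d@levels, dim(d@levels), ng)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  feats <- NULL
  nd <- dim(counts)[3]
  for (a in seq_len(nd)) {
    C <- matrix(counts[, , a], ng, ng)
    tot <- sum(C)
    if (tot == 0) next
    P <- C / tot
    px <- rowSums(P)
    mu <- sum(seq_len(ng) * px)
    sig2 <- sum((seq_len(ng) - mu)^2 * px)
    k.diff <- abs(i - j)
    pd <- vapply(0:(ng - 1), function(k) sum(P[k.diff == k]), numeric(1))
    k.sum <- i + j
    ps <- vapply(2:(2 * ng), function(k) sum(P[k.sum == k]), numeric(1))
    DA <- sum((0:(ng - 1)) * pd)
    HXY <- .entropy2(P)
    pxy <- outer(px, px)
    pos <- P > 0
    HXY1 <- -sum(P[pos] * log2(pmax(pxy[pos], .Machine$double.xmin)))
    HXY2 <- .entropy2(pxy)
    HX <- .entropy2(px)
    f <- c(
      Autocorrelation = sum(i * j * P),
      JointAverage = mu,
      ClusterProminence = sum((i + j - 2 * mu)^4 * P),
      ClusterShade = sum((i + j - 2 * mu)^3 * P),
      ClusterTendency = sum((i + j - 2 * mu)^2 * P),
      Contrast = sum((i - j)^2 * P),
      Correlation = if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1,
      DifferenceAverage = DA,
      DifferenceEntropy = .entropy2(pd),
      DifferenceVariance = sum(((0:(ng - 1)) - DA)^2 * pd),
      JointEnergy = sum(P^2),
      JointEntropy = HXY,
      Imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
      Imc2 = if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0,
      Idm = sum(P / (1 + (i - j)^2)),
      Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
      Id = sum(P / (1 + abs(i - j))),
      Idn = sum(P / (1 + abs(i - j) / ng)),
      InverseVariance = if (ng > 1)
        sum(pd[-1] / (seq_len(ng - 1))^2) else 0,
      MaximumProbability = max(P),
      SumEntropy = .entropy2(ps),
      SumSquares = sum((i - mu)^2 * P))
    feats <- rbind(feats, f)
  }
  if (is.null(feats))
    stop("no voxel pairs in any direction; ROI too small for GLCM",
         call. = FALSE)
  colMeans(feats)
}

.rlFeatures <- function(P, nVoxels, prefix) {
  ## shared formulas of the run-length / size-zone families; P is a
  ## level x size matrix of counts
  ii <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  jj <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  Nr <- sum(P)
  p <- P / Nr
  mu.i <- sum(ii * p)
  mu.j <- sum(jj * p)
  v <- c(sum(P / jj^2), sum(P * jj^2),
         sum(rowSums(P)^2), sum(rowSums(P)^2) / Nr,
         sum(colSums(P)^2), sum(colSums(P)^2) / Nr,
         Nr / nVoxels,
         sum((ii - mu.i)^2 * p), sum((jj - mu.j)^2 * p),
         .entropy2(p),
         sum(P / ii^2), sum(P * ii^2),
         sum(P / (ii^2 * jj^2)), sum(P * ii^2 / jj^2),
         sum(P * jj^2 / ii^2), sum(P * ii^2 * jj^2))
  v[c(1:2, 11:16)] <- v[c(1:2, 11:16)] / Nr
  setNames(v, prefix)
}

.GLRLM_NAMES <- c("ShortRunEmphasis", "LongRunEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
  "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy",
  "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
  "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

.GLSZM_NAMES <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
  "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
  "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

#' Gray-level run-length matrix features (16 features)
#'
#' Runs are counted along the 13 unique 3D directions; features are
#' computed per direction and averaged.
#'
#' @param d a \linkS4class{DiscretizedROI}.
#' @return named numeric vector of length 16.
#' @export
glrlmFeatures <- function(d) {
  counts <- .cppGLRLM(d@levels, dim(d@levels), d@nLevels)
  nVox <- sum(d@levels > 0L)
  feats <- NULL
  for (a in seq_len(dim(counts)[3])) {
    P <- counts[, , a, drop = FALSE]
    dim(P) <- dim(counts)[1:2]
    if (sum(P) == 0) next
    feats <- rbind(feats, .rlFeatures(P, nVox, .GLRLM_NAMES))
  }
  colMeans(feats)
}

#' Gray-level size-zone matrix features (16 features)
#'
#' Zones are maximal 26-connected components of equal gray level; a single
#' matrix is built for the whole ROI (no directionality).
#'
#' @param d a \linkS4class{DiscretizedROI}.
#' @return named numeric vector of length 16.
#' @export
glszmFeatures <- function(d) {
  z <- .cppGLSZM(d@levels, dim(d@levels))
  nVox <- sum(d@levels > 0L)
  maxSize <- max(z$size)
  P <- matrix(0, d@nLevels, maxSize)
  for (q in seq_along(z$level))
    P[z$level[q], z$size[q]] <- P[z$level[q], z$size[q]] + 1
  .rlFeatures(P, nVox, .GLSZM_NAMES)
}

#' Gray-level dependence matrix features (14 features)
#'
#' Dependence of a voxel = 1 (itself) plus the number of 26-neighbors whose
#' gray level differs by at most \code{alpha} (default 0).
#'
#' @param d a \linkS4class{DiscretizedROI}.
#' @param alpha similarity tolerance in gray levels.
#' @return named numeric vector of length 14.
#' @export
gldmFeatures <- function(d, alpha = 0L) {
  P <- .cppGLDM(d@levels, dim(d@levels), d@nLevels, as.integer(alpha))
  ii <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  jj <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  Nz <- sum(P)
  p <- P / Nz
  mu.i <- sum(ii * p)
  mu.j <- sum(jj * p)
  c(SmallDependenceEmphasis = sum(P / jj^2) / Nz,
    LargeDependenceEmphasis = sum(P * jj^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    GrayLevelVariance = sum((ii - mu.i)^2 * p),
    DependenceVariance = sum((jj - mu.j)^2 * p),
    DependenceEntropy = .entropy2(p),
    LowGrayLevelEmphasis = sum(P / ii^2) / Nz,
    HighGrayLevelEmphasis = sum(P * ii^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (ii^2 * jj^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * ii^2 / jj^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * jj^2 / ii^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * ii^2 * jj^2) / Nz)
}

#' Neighboring gray-tone difference matrix features (5 features)
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength from the
#' 26-neighborhood mean-difference vector.  Degenerate conventions: a flat
#' ROI has Contrast = Busyness = Complexity = Strength = 0 and Coarseness
#' capped at 1e6.
#'
#' @param d a \linkS4class{DiscretizedROI}.
#' @return named numeric vector of length 5.
#' @export
ngtdmFeatures <- function(d) {
  acc <- .cppNGTDM(d@levels, dim(d@levels), d@nLevels)
  s <- acc$s
  n <- acc$n
  N <- sum(n)
  pvec <- n / N
  lv <- seq_len(d@nLevels)
  act <- which(pvec > 0)
  ngp <- length(act)
  den <- sum(pvec * s)
  coarse <- if (den > 0) 1 / den else 1e6
  coarse <- min(coarse, 1e6)
  if (ngp > 1) {
    pi.mat <- outer(pvec[act], pvec[act])
    dif2 <- outer(lv[act], lv[act], `-`)^2
    contrast <- sum(pi.mat * dif2) / (ngp * (ngp - 1)) * sum(s) / N
    ipi <- lv[act] * pvec[act]
    busyDen <- sum(abs(outer(ipi, ipi, `-`)))
    busy <- if (busyDen > 0) den / busyDen else 0
    psum <- outer(pvec[act], pvec[act], `+`)
    pss <- outer(pvec[act] * s[act], pvec[act] * s[act], `+`)
    complexity <- sum(abs(outer(lv[act], lv[act], `-`)) * pss / psum) / N
    strengthNum <- sum(psum * dif2)
    strength <- if (sum(s) > 0) strengthNum / sum(s) else 0
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = complexity, Strength = strength)
}
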