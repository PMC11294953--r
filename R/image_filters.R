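## Filtered-image generation: each MRI sequence yields 12 derived images
## (4 undecimated wavelet subbands, Laplacian of Gaussian at sigma = 2..5 mm,
## and 4 monotone intensity transforms) in addition to the original, so that
## the 6 intensity feature classes are computed on 13 images in all.

#' The 13 image types (original + 12 derived)
#' @export
IMAGE_TYPES <- c("original",
                 "wavelet-LL", "wavelet-LH", "wavelet-HL", "wavelet-HH",
                 "log-sigma-2", "log-sigma-3", "log-sigma-4", "log-sigma-5",
                 "square", "squareroot", "logarithm", "exponential")

## Decomposition filter banks (standard published coefficients).
.WAVELET_FILTERS <- list(
  coif1 = list(
    lo = c(-0.015655728135791993, -0.07273261951252645,
            0.3848648468648578,    0.8525720202116004,
            0.3378976624574818,   -0.07273261951252645),
    hi = c( 0.07273261951252645,   0.3378976624574818,
           -0.8525720202116004,    0.3848648468648578,
            0.07273261951252645,  -0.015655728135791993)),
  haar = list(
    lo = c(0.7071067811865476, 0.7071067811865476),
    hi = c(-0.7071067811865476, 0.7071067811865476)),
  db2 = list(
    lo = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079,  0.48296291314453416),
    hi = c(-0.48296291314453416, 0.8365163037378079,
           -0.2241438680420134, -0.12940952255126037)))

## Mirror reflection of out-of-range indices (no edge repetition):
## index 0 -> 2, index N+1 -> N-1.
.reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  i <- ifelse(i >= n, period - i, i)
  i + 1L
}

## Convolution along one axis as a banded-matrix multiply.  `kernel` has
## taps at integer offsets -r..r; boundary is mirror or periodic.
.axisMatrix <- function(n, kernel, boundary = c("mirror", "periodic")) {
  boundary <- match.arg(boundary)
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    src <- seq_len(n) + off
    src <- if (boundary == "mirror") .reflectIndex(src, n)
           else ((src - 1L) %% n) + 1L
    M[cbind(seq_len(n), src)] <- M[cbind(seq_len(n), src)] + kernel[t]
  }
  M
}

## One-sided (causal-indexed) circular correlation matrix used by the
## undecimated wavelet transform: y[i] = sum_k h[k] x[(i + k - 1) mod n].
.circularMatrix <- function(n, h) {
  M <- matrix(0, n, n)
  for (k in seq_along(h)) {
    src <- ((seq_len(n) + k - 2L) %% n) + 1L
    M[cbind(seq_len(n), src)] <- M[cbind(seq_len(n), src)] + h[k]
  }
  M
}

.convolveAxis <- function(vol, M, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  dp <- dim(v)
  out <- M %*% matrix(v, nrow = dp[1])
  out <- array(out, dim = dp)
  aperm(out, order(perm))
}

#' Laplacian-of-Gaussian filtered image
#'
#' Convolves the volume with the 3D Laplacian-of-Gaussian kernel of scale
#' \code{sigmaMM} (in millimetres, converted to voxel units via the
#' spacing).  The kernel is evaluated analytically, factored into its three
#' separable axis terms, truncated at six sigma per axis, with mirror
#' padding at the volume boundary.
#'
#' @param volume numeric 3D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param sigmaMM filter scale in mm (> 0).
#' @return numeric 3D array of the same shape.
#' @export
logFilter <- function(volume, spacing, sigmaMM) {
  stopifnot(length(dim(volume)) == 3L, sigmaMM > 0, all(spacing > 0))
  if (any(!is.finite(volume)))
    stop("volume contains non-finite voxels", call. = FALSE)
  if (sigmaMM < max(spacing) / 2)
    warning("LoG sigma ", sigmaMM, " mm is below half the largest voxel ",
            "dimension; filter scale is under-resolved")
  sig <- sigmaMM / spacing                      # per-axis sigma in voxels
  g  <- vector("list", 3L)
  g2 <- vector("list", 3L)
  for (a in 1:3) {
    r <- ceiling(6 * sig[a])
    t <- (-r):r
    ga <- exp(-t^2 / (2 * sig[a]^2)) / (sig[a] * sqrt(2 * pi))
    g[[a]]  <- ga
    g2a <- (t^2 - sig[a]^2) / sig[a]^4 * ga
    ## zero-sum correction so the response to affine inputs vanishes
    g2[[a]] <- g2a - mean(g2a)
  }
  d <- dim(volume)
  Mg  <- lapply(1:3, function(a) .axisMatrix(d[a], g[[a]], "mirror"))
  Mg2 <- lapply(1:3, function(a) .axisMatrix(d[a], g2[[a]], "mirror"))
  out <- array(0, dim = d)
  for (a in 1:3) {
    term <- volume
    for (b in 1:3)
      term <- .convolveAxis(term, if (b == a) Mg2[[b]] else Mg[[b]], b)
    out <- out + term
  }
  out
}

#' Undecimated slice-wise wavelet subbands
#'
#' One-level undecimated 2D wavelet transform applied slice-by-slice along
#' the third (axial) array axis with periodic boundary handling, producing
#' four subband volumes of the original shape.  The first subband letter is
#' the filter applied along the first array axis, the second letter along
#' the second axis (L = low-pass, H = high-pass).
#'
#' @param volume numeric 3D array.
#' @param family wavelet family: \code{"coif1"} (default), \code{"haar"}
#'   or \code{"db2"}.
#' @return named list of four arrays: \code{LL, LH, HL, HH}.
#' @export
waveletSubbands <- function(volume, family = "coif1") {
  stopifnot(length(dim(volume)) == 3L)
  if (any(!is.finite(volume)))
    stop("volume contains non-finite voxels", call. = FALSE)
  fb <- .WAVELET_FILTERS[[family]]
  if (is.null(fb))
    stop("unknown wavelet family: ", family, " (available: ",
         paste(names(.WAVELET_FILTERS), collapse = ", "), ")",
         call. = FALSE)
  d <- dim(volume)
  M1lo <- .circularMatrix(d[1], fb$lo); M1hi <- .circularMatrix(d[1], fb$hi)
  M2lo <- .circularMatrix(d[2], fb$lo); M2hi <- .circularMatrix(d[2], fb$hi)
  out <- list(LL = array(0, d), LH = array(0, d),
              HL = array(0, d), HH = array(0, d))
  for (k in seq_len(d[3])) {
    sl <- volume[, , k]
    lo1 <- M1lo %*% sl
    hi1 <- M1hi %*% sl
    out$LL[, , k] <- lo1 %*% t(M2lo)
    out$LH[, , k] <- lo1 %*% t(M2hi)
    out$HL[, , k] <- hi1 %*% t(M2lo)
    out$HH[, , k] <- hi1 %*% t(M2hi)
  }
  out
}

#' Range-preserving pointwise intensity transforms
#'
#' Square, square root, logarithm, and exponential maps, each rescaled so
#' the output maximum absolute value equals that of the input (with m the
#' input max-abs): square \eqn{x^2/m}; square root
#' \eqn{sign(x)\sqrt{m|x|}}; logarithm
#' \eqn{sign(x)\,m\,\log(|x|+1)/\log(m+1)}; exponential
#' \eqn{e^{x \log(m)/m}}.  All are monotone on the value range of typical
#' MRI intensities; an all-zero volume maps to all-zero outputs.
#'
#' @param volume numeric 3D array.
#' @return named list of four arrays:
#'   \code{square, squareroot, logarithm, exponential}.
#' @export
intensityTransforms <- function(volume) {
  stopifnot(length(dim(volume)) == 3L)
  if (any(!is.finite(volume)))
    stop("volume contains non-finite voxels", call. = FALSE)
  m <- max(abs(volume))
  if (m == 0) {
    z <- array(0, dim(volume))
    return(list(square = z, squareroot = z, logarithm = z,
                exponential = z))
  }
  list(square      = volume^2 / m,
       squareroot  = sign(volume) * sqrt(m * abs(volume)),
       logarithm   = sign(volume) * m * log(abs(volume) + 1) / log(m + 1),
       exponential = exp(volume * log(m) / m))
}

#' Generate the 12 derived images for one sequence
#'
#' @param volume numeric 3D array (one MRI sequence).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param waveletFamily wavelet family for the subband images.
#' @param logSigmasMM LoG scales in mm (default 2, 3, 4, 5).
#' @return named list of 12 arrays, in the fixed image-type order
#'   \code{wavelet-LL, wavelet-LH, wavelet-HL, wavelet-HH, log-sigma-2,
#'   log-sigma-3, log-sigma-4, log-sigma-5, square, squareroot, logarithm,
#'   exponential}.
#' @export
deriveImages <- function(volume, spacing, waveletFamily = "coif1",
                         logSigmasMM = c(2, 3, 4, 5)) {
  if (any(!is.finite(volume)))
    stop("volume contains non-finite voxels", call. = FALSE)
  wav <- waveletSubbands(volume, family = waveletFamily)
  logs <- lapply(logSigmasMM, function(s) logFilter(volume, spacing, s))
  names(logs) <- paste0("log-sigma-", logSigmasMM)
  it <- intensityTransforms(volume)
  out <- c(list("wavelet-LL" = wav$LL, "wavelet-LH" = wav$LH,
                "wavelet-HL" = wav$HL, "wavelet-HH" = wav$HH),
           logs,
           list(square = it$square, squareroot = it$squareroot,
                logarithm = it$logarithm, exponential = it$exponential))
  stopifnot(identical(names(out), IMAGE_TYPES[-1]))
  out
}
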