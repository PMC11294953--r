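# Small in-code fixtures shared by the tests.

# cube mask with a given value block inside a zero background
smallMask <- function(dims = c(5L, 5L, 5L), inner = 2:4) {
  m <- array(FALSE, dims)
  m[inner, inner, inner] <- TRUE
  m
}

asROI <- function(mask, kind = "WT", spacing = c(1, 1, 1)) {
  new("ROIMask", voxels = mask, roiKind = kind, spacing = spacing)
}

# digitized ball of given radius (voxels), isotropic 1 mm
ballROI <- function(r = 10L) {
  n <- 2L * r + 5L
  ctr <- (n + 1) / 2
  ax <- seq_len(n)
  d2 <- outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`)
  asROI(array(d2 <= r^2 + 1e-9, c(n, n, n)))
}

# FETS segmentation with all three labels and its study, small enough for
# fast extraction
tinyStudy <- function(seed = 1L, shape = c(32L, 32L, 32L)) {
  sim <- simulateVolumeCohort(
    nPatients = 1L, mutatedFraction = 0.5, volumeShape = shape,
    radiiED = c(8, 9), radiiET = c(5, 6), radiiNCR = c(2, 3),
    seed = seed)
  sim$studies[[1]]
}

# write one synthetic study to NIfTI + manifest, return manifest row
writtenCohort <- function(n = 1L, dir = withr::local_tempdir(),
                          seed = 1L, shape = c(32L, 32L, 32L)) {
  sim <- simulateVolumeCohort(
    nPatients = n, mutatedFraction = 0.5, volumeShape = shape,
    radiiED = c(8, 9), radiiET = c(5, 6), radiiNCR = c(2, 3),
    seed = seed, dir = dir)
  sim
}
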