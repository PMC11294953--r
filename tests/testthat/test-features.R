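test_that("fixed-bin-width discretization follows the floor formula", {
  vol <- array(c(0, 24.9, 25, 50, rep(0, 4)), c(2, 2, 2))
  mask <- array(rep(c(TRUE, FALSE), each = 4), c(2, 2, 2))
  d <- discretizeROI(vol, mask, 25)
  expect_identical(as.integer(d@levels[mask]), c(1L, 1L, 2L, 3L))
  expect_identical(d@nLevels, 3L)
  ## constant ROI: single level
  dc <- discretizeROI(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 25)
  expect_identical(dc@nLevels, 1L)
  expect_true(all(dc@levels == 1L))
  expect_error(discretizeROI(vol, mask, 0), "positive")
  expect_error(discretizeROI(vol, array(FALSE, c(2, 2, 2)), 25), "empty")
})

test_that("first-order features match hand arithmetic", {
  vol <- array(c(1, 2, 3, 4, rep(0, 4)), c(2, 2, 2))
  mask <- array(rep(c(TRUE, FALSE), each = 4), c(2, 2, 2))
  fo <- firstOrderFeatures(vol, mask, binWidth = 1)
  expect_length(fo, 18L)
  expect_equal(unname(fo["Mean"]), 2.5)
  expect_equal(unname(fo["Variance"]), 1.25)   # population variance
  expect_equal(unname(fo["Range"]), 3)
  expect_equal(unname(fo["Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(fo["RootMeanSquared"]), sqrt(30 / 4))
  expect_equal(unname(fo["Median"]), 2.5)
  ## four distinct levels at bin width 1: flat histogram
  expect_equal(unname(fo["Entropy"]), 2)
  expect_equal(unname(fo["Uniformity"]), 0.25)
})

test_that("constant ROI first-order conventions hold", {
  fo <- firstOrderFeatures(array(9, c(3, 3, 3)), array(TRUE, c(3, 3, 3)))
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Entropy"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  expect_equal(unname(fo["Skewness"]), 0)
  expect_equal(unname(fo["Kurtosis"]), 0)
})

test_that("GLCM counts equal brute-force pair enumeration on a 2D toy", {
  ## [[1,1,2],[1,2,2]] as a 1-slice volume
  lev <- array(0L, c(2, 3, 1))
  lev[1, , 1] <- c(1L, 1L, 2L)
  lev[2, , 1] <- c(1L, 2L, 2L)
  got <- GliomaRadiomics:::.cppGLCM(lev, dim(lev), 2L)
  expect_equal(unclass(got), oracleGLCM(lev, 2L), ignore_attr = TRUE)
  ## in-plane offset (0,1,0) by hand: pairs (1,1)x1, (1,2)x2, (2,2)x1,
  ## doubled by symmetrization
  inplane <- got[, , 3]
  expect_equal(inplane, matrix(c(2, 2, 2, 2), 2, 2))
})

test_that("texture matrices agree with brute-force enumeration", {
  set.seed(17)
  for (rep in 1:30) {
    ra <- randomLevelArray()
    lev <- ra$lev; ng <- ra$ng; d <- ra$dims
    expect_equal(unclass(GliomaRadiomics:::.cppGLCM(lev, d, ng)),
                 oracleGLCM(lev, ng), ignore_attr = TRUE)
    expect_equal(unclass(GliomaRadiomics:::.cppGLRLM(lev, d, ng))[, seq_len(max(d)), ],
                 oracleGLRLM(lev, ng), ignore_attr = TRUE)
    z <- GliomaRadiomics:::.cppGLSZM(lev, d)
    zo <- oracleGLSZM(lev)
    expect_equal(sort(paste(z$level, z$size)),
                 sort(paste(zo[, "level"], zo[, "size"])))
    expect_equal(unclass(GliomaRadiomics:::.cppGLDM(lev, d, ng, 0L)),
                 oracleGLDM(lev, ng), ignore_attr = TRUE)
    nt <- GliomaRadiomics:::.cppNGTDM(lev, d, ng)
    no <- oracleNGTDM(lev, ng)
    expect_equal(as.numeric(nt$s), no$s)
    expect_equal(as.numeric(nt$n), no$n)
  }
})

test_that("GLRLM finds the hand-enumerated runs of a 1D row", {
  lev <- array(c(1L, 1L, 1L, 2L), c(4, 1, 1))
  rl <- GliomaRadiomics:::.cppGLRLM(lev, c(4L, 1L, 1L), 2L)
  axial <- rl[, , 9]  # direction (1,0,0)
  expect_equal(axial[1, 3], 1)  # level 1, run length 3
  expect_equal(axial[2, 1], 1)  # level 2, run length 1
  expect_equal(sum(axial), 2)
})

test_that("a constant ROI is one zone and degenerate conventions hold", {
  d <- discretizeROI(array(5, c(3, 4, 2)), array(TRUE, c(3, 4, 2)), 25)
  z <- GliomaRadiomics:::.cppGLSZM(d@levels, dim(d@levels))
  expect_equal(length(z$size), 1L)
  expect_equal(z$size[1], 24L)
  g <- glcmFeatures(d)
  expect_equal(unname(g["Correlation"]), 1)
  expect_equal(unname(g["MaximumProbability"]), 1)
  expect_equal(unname(g["JointEntropy"]), 0)
})

test_that("GLSZM zone sizes conserve the ROI voxel count", {
  set.seed(23)
  for (rep in 1:10) {
    ra <- randomLevelArray()
    z <- GliomaRadiomics:::.cppGLSZM(ra$lev, ra$dims)
    expect_equal(sum(z$size), sum(ra$lev > 0))
  }
})

test_that("feature class cardinalities match the published inventory", {
  st <- tinyStudy()
  roi <- makeROI(st@segmentation, "WT", st@spacing)
  vol <- st@sequences$T1
  d <- discretizeROI(vol, roi, 25)
  expect_length(firstOrderFeatures(vol, roi), 18L)
  expect_length(shapeFeatures(roi), 14L)
  expect_length(glcmFeatures(d), 22L)
  expect_length(glrlmFeatures(d), 16L)
  expect_length(glszmFeatures(d), 16L)
  expect_length(gldmFeatures(d), 14L)
  expect_length(ngtdmFeatures(d), 5L)
})

test_that("intensity features are invariant to ROI-preserving translation", {
  set.seed(31)
  vol <- array(runif(14^3, 50, 200), c(14, 14, 14))
  mask <- array(FALSE, c(14, 14, 14))
  mask[3:6, 3:6, 3:6] <- TRUE
  shift <- c(4L, 2L, 5L)
  vol2 <- array(0, c(14, 14, 14))
  mask2 <- array(FALSE, c(14, 14, 14))
  vol2[3:6 + shift[1], 3:6 + shift[2], 3:6 + shift[3]] <-
    vol[3:6, 3:6, 3:6]
  mask2[3:6 + shift[1], 3:6 + shift[2], 3:6 + shift[3]] <- TRUE
  expect_equal(firstOrderFeatures(vol, mask),
               firstOrderFeatures(vol2, mask2))
  d1 <- discretizeROI(vol, mask, 25)
  d2 <- discretizeROI(vol2, mask2, 25)
  expect_equal(glcmFeatures(d1), glcmFeatures(d2))
  expect_equal(ngtdmFeatures(d1), ngtdmFeatures(d2))
})

test_that("first-order Mean/Min/Max are equivariant under intensity shift", {
  set.seed(33)
  vol <- array(runif(6^3, 10, 90), c(6, 6, 6))
  mask <- array(TRUE, c(6, 6, 6))
  f0 <- firstOrderFeatures(vol, mask)
  f1 <- firstOrderFeatures(vol + 13.5, mask)
  for (nm in c("Mean", "Minimum", "Maximum", "Median"))
    expect_equal(unname(f1[nm] - f0[nm]), 13.5)
  for (nm in c("Variance", "Range", "MeanAbsoluteDeviation"))
    expect_equal(unname(f1[nm]), unname(f0[nm]))
})

test_that("full extraction yields 1197 features per ROI per sequence", {
  st <- tinyStudy()
  fv <- extractFeatures(st)
  expect_length(fv, 2L * 4L * 1197L)
  expect_length(grep("^ROI1_T1_", names(fv)), 1197L)
  expect_length(grep("^ROI2_FLAIR_", names(fv)), 1197L)
  expect_false(anyNA(fv))
  expect_true(all(is.finite(fv)))
  expect_false(anyDuplicated(names(fv)) > 0)
  ## per-class counts inside one (ROI, sequence) block
  nm <- grep("^ROI1_T1_", names(fv), value = TRUE)
  cls <- sub("^ROI1_T1_[^_]+_([a-z]+)_.*$", "\\1", nm)
  expect_equal(sum(cls == "shape"), 14L)
  expect_equal(sum(cls == "firstorder"), 18L * 13L)
  expect_equal(sum(cls == "glcm"), 22L * 13L)
  expect_equal(sum(cls == "glrlm"), 16L * 13L)
  expect_equal(sum(cls == "glszm"), 16L * 13L)
  expect_equal(sum(cls == "gldm"), 14L * 13L)
  expect_equal(sum(cls == "ngtdm"), 5L * 13L)
})

test_that("WT-only segmentations yield one ROI's worth of columns", {
  st <- tinyStudy()
  wtSeg <- LabeledMask(
    array(as.integer(st@segmentation@voxels > 0L),
          dim(st@segmentation@voxels)), "WT_ONLY")
  st2 <- MRIStudy(st@patientId, st@sequences, st@spacing, wtSeg)
  fv <- extractFeatures(st2)
  expect_length(fv, 4L * 1197L)
  expect_identical(attr(fv, "missingROIs"), "NONENH")
  expect_length(grep("^ROI2_", names(fv)), 0L)
})
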