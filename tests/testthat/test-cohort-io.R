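test_that("a written synthetic study round-trips through loadStudy", {
  dir <- withr::local_tempdir()
  sim <- writtenCohort(dir = dir)
  man <- readManifest(file.path(dir, "manifest.csv"))
  st <- loadStudy(man[1, ])
  expect_s4_class(st, "MRIStudy")
  expect_identical(sort(names(st@sequences)),
                   sort(c("T1", "T1c", "T2", "FLAIR")))
  expect_identical(dim(st@sequences$T1), c(32L, 32L, 32L))
  expect_equal(st@spacing, c(1, 1, 1))
  expect_equal(st@segmentation@scheme, "FETS")
  ## voxel data survives the round trip
  expect_equal(as.vector(st@sequences$T2),
               as.vector(sim$studies[[1]]@sequences$T2),
               tolerance = 1e-6)
  expect_identical(as.integer(st@segmentation@voxels),
                   as.integer(sim$studies[[1]]@segmentation@voxels))
})

test_that("loadStudy rejects missing files and mismatched shapes", {
  dir <- withr::local_tempdir()
  sim <- writtenCohort(dir = dir)
  row <- as.list(sim$manifest[1, ])
  bad <- row
  bad$flair <- file.path(dir, "nonexistent.nii.gz")
  expect_error(loadStudy(bad), "nonexistent")
  ## truncated segmentation: different shape
  seg <- RNifti::readNifti(row$seg)
  short <- as.array(seg)[, , 1:31]
  RNifti::writeNifti(RNifti::asNifti(short, pixdim = c(1, 1, 1)),
                     file.path(dir, "short_seg.nii.gz"))
  bad2 <- row
  bad2$seg <- file.path(dir, "short_seg.nii.gz")
  expect_error(loadStudy(bad2), "not coregistered")
})

test_that("segmentations with labels outside the scheme fail validation", {
  vox <- array(0L, c(4, 4, 4))
  vox[2, 2, 2] <- 3L
  expect_error(LabeledMask(vox, "FETS"), "labels outside")
  expect_error(LabeledMask(array(0L, c(4, 4, 4)), "FETS"), "nonzero")
  vox2 <- array(0L, c(4, 4, 4))
  vox2[2, 2, 2] <- 2L
  expect_error(LabeledMask(vox2, "WT_ONLY"), "labels outside")
})

test_that("ROI construction follows the label schemes", {
  vox <- array(0L, c(6, 6, 6))
  vox[2:3, 2:3, 2:3] <- 1L   # 8 voxels NCR
  vox[4, 2:4, 2] <- 2L       # 3 voxels NET/ED
  vox[5, 5, 2:5] <- 4L       # 4 voxels ET
  for (scheme in c("FETS", "UCSF")) {
    m <- LabeledMask(vox, scheme)
    wt <- makeROI(m, "WT")
    ne <- makeROI(m, "NONENH")
    expect_equal(sum(wt@voxels), 15)
    expect_equal(sum(ne@voxels), 11)
    ## NONENH excludes every label-4 voxel
    expect_false(any(ne@voxels & (vox == 4L)))
    ## disjoint union: WT = NONENH + ET exactly
    expect_equal(sum(wt@voxels), sum(ne@voxels) + sum(vox == 4L))
    expect_true(all(wt@voxels == (ne@voxels | vox == 4L)))
  }
})

test_that("WT-only segmentations support only the WT ROI", {
  vox <- array(0L, c(4, 4, 4))
  vox[2:3, 2:3, 2:3] <- 1L
  m <- LabeledMask(vox, "WT_ONLY")
  expect_equal(sum(makeROI(m, "WT")@voxels), 8)
  expect_error(makeROI(m, "NONENH"), "WT_ONLY")
})

test_that("ROI construction is idempotent", {
  vox <- array(0L, c(5, 5, 5))
  vox[2:4, 2:4, 2:4] <- sample(c(1L, 2L, 4L), 27, replace = TRUE)
  m <- LabeledMask(vox, "FETS")
  expect_identical(makeROI(m, "WT")@voxels, makeROI(m, "WT")@voxels)
  expect_identical(makeROI(m, "NONENH")@voxels,
                   makeROI(m, "NONENH")@voxels)
})

test_that("feature tables round-trip losslessly through CSV", {
  set.seed(3)
  mat <- matrix(rnorm(30) * 10^sample(-8:8, 30, replace = TRUE), 3, 10,
                dimnames = list(paste0("P", 1:3), paste0("feat", 1:10)))
  fs <- RadiomicsFeatureSet(mat, c(1L, 0L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(fs, path)
  back <- readFeatureTable(path)
  expect_identical(colnames(featureMatrix(back)), colnames(mat))
  expect_identical(rownames(featureMatrix(back)), rownames(mat))
  expect_equal(featureMatrix(back), mat, tolerance = 1e-12)
  expect_identical(unname(idhLabels(back)), c(1L, 0L, 1L))
})

test_that("malformed feature tables are rejected", {
  mat <- matrix(1:4, 2, 2,
                dimnames = list(c("a", "b"), c("x", "x")))
  expect_error(RadiomicsFeatureSet(mat, c(0L, 1L)), "duplicated")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,IDH,f1", path)  # header only, no rows
  expect_error(readFeatureTable(path), "empty")
  expect_error(RadiomicsFeatureSet(matrix(numeric(0), 0, 0), integer(0)),
               "empty")
})
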