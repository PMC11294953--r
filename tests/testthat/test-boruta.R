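test_that("a separable feature is confirmed and noise stays out", {
  set.seed(1)
  n <- 200L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sig = y + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("N", 1:20))))
  dec <- borutaSelect(X, y, seed = 11)
  expect_identical(dec@decisions[["sig"]], "confirmed")
  ## finite-sample chance correlations can leave the odd noise feature
  ## undecided, but the confirmed set stays essentially clean
  expect_lte(sum(dec@decisions[-1] == "confirmed"), 1L)
})

test_that("statuses partition the feature set and respect hit bounds", {
  tc <- simulateTabularCohort(80, 15, 2, 1.0, 1, seed = 41)
  dec <- borutaSelect(tc$X, tc$y, maxIter = 12L, seed = 2, nTrees = 100)
  expect_identical(sort(names(dec@decisions)), sort(colnames(tc$X)))
  expect_true(all(dec@decisions %in%
                    c("confirmed", "rejected", "tentative")))
  expect_true(all(dec@hits <= dec@nIterations))
  expect_s4_class(dec, "BorutaDecision")
})

test_that("identical seeds give bit-identical decisions", {
  tc <- simulateTabularCohort(100, 20, 3, 1.2, 1, seed = 7)
  d1 <- borutaSelect(tc$X, tc$y, seed = 99, maxIter = 20, nTrees = 100)
  d2 <- borutaSelect(tc$X, tc$y, seed = 99, maxIter = 20, nTrees = 100)
  expect_identical(d1@decisions, d2@decisions)
  expect_identical(d1@hits, d2@hits)
  expect_identical(d1@nIterations, d2@nIterations)
})

test_that("constant columns are rejected with a warning", {
  tc <- simulateTabularCohort(60, 5, 1, 1.5, 1, seed = 13)
  X <- cbind(tc$X, flat = rep(3, 60))
  expect_warning(dec <- borutaSelect(X, tc$y, maxIter = 10, seed = 1,
                                     nTrees = 50), "constant")
  expect_identical(dec@decisions[["flat"]], "rejected")
})

test_that("input contracts are enforced", {
  tc <- simulateTabularCohort(40, 4, 0, 0, 1, seed = 3)
  expect_error(borutaSelect(tc$X, tc$y, maxIter = 5), "at least 10")
  expect_error(borutaSelect(tc$X, rep(1L, 40)), "binary")
  Xna <- tc$X; Xna[1, 1] <- NA
  expect_error(borutaSelect(Xna, tc$y), "missing")
})

test_that("multi-subset selection is deterministic and thresholded", {
  tc <- simulateTabularCohort(120, 30, 3, 1.5, 2, seed = 19)
  s1 <- suppressWarnings(
    multiSubsetSelect(tc$X, tc$y, nSubsets = 4, seed = 5,
                      maxIter = 25, nTrees = 100))
  s2 <- suppressWarnings(
    multiSubsetSelect(tc$X, tc$y, nSubsets = 4, seed = 5,
                      maxIter = 25, nTrees = 100))
  expect_identical(s1@counts, s2@counts)
  expect_true(all(s1@counts <= s1@nSubsets))
  ## monotonicity: the relevant set can only shrink as the threshold rises
  hi <- new("SelectionFrequency", counts = s1@counts,
            nSubsets = s1@nSubsets, thresholdFraction = 1.0,
            fallbackK = 0L)
  lo <- new("SelectionFrequency", counts = s1@counts,
            nSubsets = s1@nSubsets, thresholdFraction = 0.5,
            fallbackK = 0L)
  hiRel <- names(s1@counts)[s1@counts / s1@nSubsets >= 1.0]
  expect_true(all(hiRel %in% relevantFeatures(lo)))
})

test_that("empty relevant sets warn and fall back to top-k", {
  tc <- simulateTabularCohort(60, 10, 0, 0, 1, seed = 23)
  expect_warning(
    sel <- multiSubsetSelect(tc$X, tc$y, nSubsets = 2, seed = 2,
                             maxIter = 10, nTrees = 50, fallbackK = 3),
    "threshold")
  expect_length(relevantFeatures(sel), 3L)
})

test_that("per-ROI selection returns WT, NONENH and combined pools", {
  set.seed(29)
  n <- 40L
  mk <- function(prefix, p) {
    m <- matrix(rnorm(n * p), n, p)
    colnames(m) <- paste0(prefix, "_T1_original_firstorder_F", seq_len(p))
    m
  }
  y <- rep(c(0L, 1L), each = n / 2)
  mat <- cbind(mk("ROI1", 6), mk("ROI2", 4))
  mat[y == 1, 1] <- mat[y == 1, 1] + 2   # one informative WT feature
  rownames(mat) <- paste0("P", seq_len(n))
  fs <- RadiomicsFeatureSet(mat, y)
  res <- suppressWarnings(
    selectForROISets(fs, nSubsets = 2, seed = 3, maxIter = 10,
                     nTrees = 50))
  expect_identical(names(res), c("WT", "NONENH", "combined"))
  expect_length(res$WT@counts, 6L)
  expect_length(res$NONENH@counts, 4L)
  expect_length(res$combined@counts, 10L)
  ## WT-only request returns only the WT pool
  resWT <- suppressWarnings(
    selectForROISets(fs, rois = "WT", nSubsets = 2, seed = 3,
                     maxIter = 10, nTrees = 50))
  expect_identical(names(resWT), "WT")
  ## missing ROI columns error by name
  fsWT <- RadiomicsFeatureSet(mat[, 1:6], y)
  expect_error(
    suppressWarnings(selectForROISets(fsWT, nSubsets = 2, seed = 3,
                                      maxIter = 10, nTrees = 50)),
    "NONENH")
})
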