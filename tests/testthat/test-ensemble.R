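test_that("balanced subsets are exact 1:1 and keep every minority sample", {
  y <- c(rep(1L, 94), rep(0L, 133))   # the training-cohort class counts
  subsets <- makeBalancedSubsets(y, 6, seed = 2)
  for (s in subsets) {
    expect_length(s$indices, 188L)
    expect_true(all(which(y == 1L) %in% s$indices))
    expect_equal(sum(y[s$indices]), 94L)          # exactly 1:1
    expect_false(anyDuplicated(s$indices) > 0)    # without replacement
  }
})

test_that("already balanced labels give permutations of all samples", {
  y <- rep(c(0L, 1L), 20)
  subsets <- makeBalancedSubsets(y, 3, seed = 4)
  for (s in subsets)
    expect_identical(sort(s$indices), seq_along(y))
})

test_that("majority samples are drawn uniformly across subsets", {
  y <- c(rep(1L, 20), rep(0L, 60))
  subsets <- makeBalancedSubsets(y, 2000, seed = 8)
  counts <- table(factor(unlist(lapply(subsets, `[[`, "indices")),
                         levels = seq_along(y)))
  majFreq <- as.numeric(counts[21:80]) / 2000
  pExp <- 20 / 60
  se <- sqrt(pExp * (1 - pExp) / 2000)
  expect_true(all(abs(majFreq - pExp) <= 3 * se + 1e-12))
})

test_that("a swapped-roles warning fires when label 1 is the majority", {
  y <- c(rep(1L, 30), rep(0L, 10))
  expect_warning(subsets <- makeBalancedSubsets(y, 2, seed = 1),
                 "swapping")
  expect_length(subsets[[1]]$indices, 20L)
})

test_that("ensemble probability is the exact member mean", {
  tc <- simulateTabularCohort(120, 8, 3, 1.5, 2, seed = 11)
  m <- trainEnsemble(tc$X, tc$y, nSubsets = 4, seed = 5,
                     hyperparams = list(numTrees = 80))
  p <- predictProbability(m, tc$X)
  probs <- vapply(m@members, function(mm)
    predict(mm, data = as.data.frame(tc$X),
            num.threads = 1)$predictions[, "1"],
    numeric(nrow(tc$X)))
  expect_equal(p, rowMeans(probs), tolerance = 1e-15)
  expect_true(all(p >= 0 & p <= 1))
  ## member order must not matter
  m2 <- m
  m2@members <- rev(m@members)
  expect_equal(predictProbability(m2, tc$X), p, tolerance = 1e-15)
})

test_that("two members with probabilities p average to their mean", {
  tc <- simulateTabularCohort(60, 4, 2, 2.0, 1, seed = 31)
  m <- trainEnsemble(tc$X, tc$y, nSubsets = 2, seed = 9,
                     hyperparams = list(numTrees = 50))
  p <- predictProbability(m, tc$X[1:5, , drop = FALSE])
  p1 <- predict(m@members[[1]], data = as.data.frame(tc$X[1:5, ]),
                num.threads = 1)$predictions[, "1"]
  p2 <- predict(m@members[[2]], data = as.data.frame(tc$X[1:5, ]),
                num.threads = 1)$predictions[, "1"]
  expect_equal(p, (p1 + p2) / 2)
})

test_that("training is deterministic and reduces to one subset cleanly", {
  tc <- simulateTabularCohort(100, 6, 2, 1.5, 3, seed = 13)
  m1 <- trainEnsemble(tc$X, tc$y, nSubsets = 1, seed = 3,
                      hyperparams = list(numTrees = 60))
  m2 <- trainEnsemble(tc$X, tc$y, nSubsets = 1, seed = 3,
                      hyperparams = list(numTrees = 60))
  expect_length(m1@members, 1L)
  expect_identical(predictProbability(m1, tc$X),
                   predictProbability(m2, tc$X))
})

test_that("perfectly separable data trains to AUC 1", {
  set.seed(17)
  n <- 80L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sep = ifelse(y == 1, 5, -5) + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 3), n, 3,
                    dimnames = list(NULL, paste0("N", 1:3))))
  m <- trainEnsemble(X, y, nSubsets = 3, seed = 7,
                     hyperparams = list(numTrees = 100))
  expect_equal(rocAUC(predictProbability(m, X), y)@auc, 1.0)
})

test_that("column mismatches are rejected with names", {
  tc <- simulateTabularCohort(60, 5, 1, 1.5, 1, seed = 19)
  m <- trainEnsemble(tc$X, tc$y, nSubsets = 2, seed = 2,
                     hyperparams = list(numTrees = 40))
  expect_error(predictProbability(m, tc$X[, 1:3]), "missing: F004")
  Xx <- cbind(tc$X, extra = 1)
  expect_error(predictProbability(m, Xx), "extra")
  expect_error(predictProbability(m, tc$X[, rev(colnames(tc$X))]),
               "order")
})

test_that("xgboost ensembles train, predict and persist", {
  tc <- simulateTabularCohort(100, 6, 3, 1.5, 2, seed = 23)
  m <- trainEnsemble(tc$X, tc$y, classifier = "xgboost", nSubsets = 3,
                     seed = 4, hyperparams = list(nrounds = 40))
  p <- predictProbability(m, tc$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(rocAUC(p, tc$y)@auc, 0.8)
  dir <- withr::local_tempdir()
  saveEnsemble(m, dir)
  m2 <- loadEnsemble(dir)
  expect_equal(predictProbability(m2, tc$X), p, tolerance = 1e-7)
})

test_that("SMOTE balances counts with on-segment synthetic points", {
  tc <- simulateTabularCohort(50, 4, 2, 1.0, 4, seed = 29)
  expect_equal(sum(tc$y == 1), 10L)
  sm <- smoteOversample(tc$X, tc$y, kNeighbors = 5, seed = 1)
  expect_equal(sum(sm$y == 1), sum(sm$y == 0))
  ## synthetic rows lie on a segment between two real minority samples
  Xm <- tc$X[tc$y == 1L, ]
  synth <- sm$X[(nrow(tc$X) + 1):nrow(sm$X), , drop = FALSE]
  onSegment <- function(s) {
    for (a in seq_len(nrow(Xm))) for (b in seq_len(nrow(Xm))) {
      if (a == b) next
      d <- Xm[b, ] - Xm[a, ]
      nz <- which(abs(d) > 1e-12)
      if (!length(nz)) next
      t <- (s[nz[1]] - Xm[a, nz[1]]) / d[nz[1]]
      if (t >= -1e-9 && t <= 1 + 1e-9 &&
          max(abs(s - (Xm[a, ] + t * d))) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, onSegment)))
  ## already balanced: unchanged
  yb <- rep(c(0L, 1L), 10)
  Xb <- matrix(rnorm(80), 20, 4)
  sb <- smoteOversample(Xb, yb, kNeighbors = 3, seed = 2)
  expect_identical(sb$X, Xb)
  expect_identical(sb$y, yb)
  expect_error(smoteOversample(tc$X, tc$y, kNeighbors = 10, seed = 1),
               "smaller than the minority")
})
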