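## Boruta all-relevant feature selection, and its aggregation over multiple
## balanced subsets of an imbalanced cohort.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Boruta shadow-feature selection
#'
#' Each iteration appends a column-wise independently permuted copy of
#' every still-active feature (the shadows), fits a random-forest impurity
#' importance estimator, and scores a real feature a "hit" when its
#' importance exceeds the maximum shadow importance.  Accumulated hits are
#' tested against Binomial(n, 1/2) with two one-sided tests at level
#' \code{alpha/2}, Bonferroni-corrected across the currently active
#' features: significantly more hits than n/2 confirms, significantly
#' fewer rejects.  Undecided features after \code{maxIter} iterations stay
#' tentative.  Constant columns are rejected up front with a warning.
#'
#' @param X numeric matrix (samples x features), no missing values.
#' @param y binary labels (0/1), at least two samples per class.
#' @param alpha significance level, default 0.05.
#' @param maxIter maximum iterations (>= 10), default 100.
#' @param seed integer seed; identical seeds give identical decisions.
#' @param nTrees trees per forest, default 300.
#' @return a \linkS4class{BorutaDecision}.
#' @export
borutaSelect <- function(X, y, alpha = 0.05, maxIter = 100L, seed = 1L,
                         nTrees = 300L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) != 2L || min(table(y)) < 2L)
    stop("y must be binary with at least two samples per class",
         call. = FALSE)
  if (maxIter < 10L) stop("maxIter must be at least 10", call. = FALSE)
  p <- ncol(X)
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("F", seq_len(p))
  colnames(X) <- fn
  status <- setNames(rep("tentative", p), fn)
  hits <- setNames(integer(p), fn)
  constant <- apply(X, 2, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warning("rejecting constant feature columns: ",
            paste(fn[constant], collapse = ", "))
    status[constant] <- "rejected"
  }
  yf <- factor(y, levels = c(0L, 1L))
  iter <- 0L
  ## the full shadow set is kept every iteration (a permuted copy of every
  ## feature), so the shadow noise floor does not weaken as features are
  ## decided
  .withSeed(seed, {
    while (iter < maxIter && any(status == "tentative")) {
      iter <- iter + 1L
      active <- names(status)[status == "tentative"]
      shadows <- apply(X, 2, sample)
      colnames(shadows) <- paste0(".shadow.", fn)
      fit <- ranger::ranger(
        x = cbind(X, shadows), y = yf, num.trees = nTrees,
        importance = "impurity", num.threads = 1L,
        seed = sample.int(.Machine$integer.max, 1L))
      imp <- fit$variable.importance
      shadowMax <- max(imp[colnames(shadows)])
      hit <- imp[active] > shadowMax
      hits[active] <- hits[active] + as.integer(hit)
      thr <- alpha / (2 * p)
      pConfirm <- pbinom(hits[active] - 1L, iter, 0.5,
                         lower.tail = FALSE)
      pReject <- pbinom(hits[active], iter, 0.5)
      status[active[pConfirm < thr]] <- "confirmed"
      status[active[pReject < thr]] <- "rejected"
    }
  })
  new("BorutaDecision", decisions = status, hits = hits,
      nIterations = max(iter, 1L), alpha = alpha)
}

#' Boruta over multiple balanced subsets
#'
#' Draws \code{nSubsets} balanced (1:1 undersampled) training subsets, runs
#' Boruta on each, and counts per feature how many subsets confirmed it.
#' Features confirmed in at least \code{thresholdFraction} of the subsets
#' form the relevant set; if that set is empty a warning is issued and
#' \code{\link{relevantFeatures}} falls back to the top \code{fallbackK}
#' features by frequency.
#'
#' @inheritParams borutaSelect
#' @param nSubsets number of balanced subsets, default 20.
#' @param thresholdFraction frequency threshold in (0, 1], default 0.5.
#' @param fallbackK fallback size when nothing reaches the threshold.
#' @return a \linkS4class{SelectionFrequency}.
#' @export
multiSubsetSelect <- function(X, y, nSubsets = 20L,
                              thresholdFraction = 0.5, seed = 1L,
                              alpha = 0.05, maxIter = 100L,
                              nTrees = 300L, fallbackK = 10L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) != 2L)
    stop("both classes must be present", call. = FALSE)
  if (nSubsets < 1L) stop("nSubsets must be >= 1", call. = FALSE)
  fn <- colnames(X)
  if (is.null(fn)) {
    fn <- paste0("F", seq_len(ncol(X)))
    colnames(X) <- fn
  }
  subsets <- makeBalancedSubsets(y, nSubsets, seed = seed)
  counts <- setNames(integer(ncol(X)), fn)
  subSeeds <- .withSeed(seed, sample.int(2^31 - 1, nSubsets))
  for (s in seq_along(subsets)) {
    idx <- subsets[[s]]$indices
    dec <- borutaSelect(X[idx, , drop = FALSE], y[idx], alpha = alpha,
                        maxIter = maxIter, seed = subSeeds[s],
                        nTrees = nTrees)
    conf <- relevantFeatures(dec)
    counts[conf] <- counts[conf] + 1L
  }
  if (!any(counts / nSubsets >= thresholdFraction))
    warning("no feature reaches the selection-frequency threshold ",
            thresholdFraction, "; relevantFeatures() will fall back to ",
            "the top ", fallbackK, " features by frequency")
  new("SelectionFrequency", counts = counts,
      nSubsets = as.integer(nSubsets),
      thresholdFraction = thresholdFraction,
      fallbackK = as.integer(fallbackK))
}

#' Run multi-subset selection per ROI and for the combined feature pool
#'
#' Mirrors the three candidate pools the framework compares: whole-tumor
#' features only, nonenhancing-region features only, and the concatenation
#' of both, each passed through multi-subset Boruta.
#'
#' @param featureSet a \linkS4class{RadiomicsFeatureSet}.
#' @param rois ROI kinds to use, default both.
#' @param ... passed to \code{\link{multiSubsetSelect}}.
#' @return named list of \linkS4class{SelectionFrequency} results with
#'   elements \code{WT}, \code{NONENH} (when requested) and
#'   \code{combined}.
#' @export
selectForROISets <- function(featureSet, rois = c("WT", "NONENH"), ...) {
  stopifnot(is(featureSet, "RadiomicsFeatureSet"))
  mat <- featureMatrix(featureSet)
  y <- idhLabels(featureSet)
  pools <- list()
  for (rk in rois) {
    pref <- paste0(.ROI_PREFIX[[rk]], "_")
    cols <- grep(pref, colnames(mat), fixed = TRUE, value = TRUE)
    cols <- cols[startsWith(cols, pref)]
    if (length(cols) == 0L)
      stop("feature table has no columns for ROI ", rk, call. = FALSE)
    pools[[rk]] <- cols
  }
  if (length(pools) > 1L)
    pools$combined <- unlist(pools, use.names = FALSE)
  lapply(pools, function(cols)
    multiSubsetSelect(mat[, cols, drop = FALSE], y, ...))
}
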