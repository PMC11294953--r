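## The two-stage training framework: (1) one classifier per balanced
## subset obtained by undersampling the majority class to a 1:1 ratio;
## (2) arithmetic averaging of the member mutated-class probabilities.

#' Draw balanced training subsets
#'
#' Each subset contains every minority-class sample plus an equal-sized
#' uniform draw (without replacement) of majority-class samples, giving an
#' exact 1:1 class ratio.  Draws are independent across subsets and
#' deterministic given the seed.  If the nominal minority class (label 1)
#' outnumbers the other, the roles are swapped with a warning.
#'
#' @param y binary labels (0/1).
#' @param nSubsets number of subsets.
#' @param seed integer seed.
#' @return list of subsets, each a list with \code{indices},
#'   \code{nMinority}, \code{nMajorityDrawn}.
#' @export
makeBalancedSubsets <- function(y, nSubsets, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) != 2L)
    stop("both classes must be present", call. = FALSE)
  idx1 <- which(y == 1L)
  idx0 <- which(y == 0L)
  if (length(idx1) > length(idx0)) {
    warning("label-1 class outnumbers label-0; swapping sampling roles")
    tmp <- idx1; idx1 <- idx0; idx0 <- tmp
  }
  if (length(idx1) < 2L)
    stop("minority class needs at least two samples", call. = FALSE)
  .withSeed(seed, lapply(seq_len(nSubsets), function(s) {
    drawn <- sample(idx0, length(idx1), replace = FALSE)
    list(indices = sample(c(idx1, drawn)),
         nMinority = length(idx1),
         nMajorityDrawn = length(idx1))
  }))
}

.fitMember <- function(X, y, classifier, hp, seed) {
  yf <- factor(y, levels = c(0L, 1L))
  if (classifier == "random_forest") {
    ranger::ranger(x = as.data.frame(X), y = yf, probability = TRUE,
                   num.trees = hp$numTrees,
                   mtry = max(1L, floor(sqrt(ncol(X)))),
                   min.node.size = hp$minNodeSize,
                   num.threads = 1L, seed = seed)
  } else {
    set.seed(seed)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = hp$maxDepth,
                    learning_rate = hp$eta,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
      nrounds = hp$nrounds, verbose = 0)
  }
}

.memberProb <- function(member, classifier, X) {
  if (classifier == "random_forest") {
    pr <- predict(member, data = as.data.frame(X),
                  num.threads = 1L)$predictions
    pr[, "1"]
  } else {
    predict(member, newdata = xgboost::xgb.DMatrix(X, nthread = 1L))
  }
}

#' Default classifier hyperparameters
#'
#' Forest: 500 trees, sqrt(p) candidate features per split, minimum node
#' size 1 (so trees can split even in small balanced subsets).  Boosting:
#' 300 rounds, depth 4, learning rate 0.1.
#'
#' @return named list.
#' @export
defaultHyperparams <- function() {
  list(numTrees = 500L, minNodeSize = 1L, nrounds = 300L, maxDepth = 4L,
       eta = 0.1)
}

#' Train the balanced-subset ensemble
#'
#' Fits one classifier per balanced subset (on that subset only).  A member
#' whose fit fails (e.g. all-constant features in its draw) is dropped with
#' a warning; training errors out if fewer than half the members survive.
#'
#' @param X numeric matrix restricted to the selected features.
#' @param y binary labels (1 = mutated).
#' @param featureNames predictor columns to use (default: all columns).
#' @param classifier \code{"random_forest"} (default) or \code{"xgboost"}.
#' @param nSubsets number of balanced subsets, default 20.
#' @param hyperparams see \code{\link{defaultHyperparams}}.
#' @param seed integer seed.
#' @param decisionThreshold probability cut for class calls, default 0.5.
#' @return a \linkS4class{BalancedEnsemble}.
#' @export
trainEnsemble <- function(X, y, featureNames = colnames(X),
                          classifier = c("random_forest", "xgboost"),
                          nSubsets = 20L,
                          hyperparams = defaultHyperparams(),
                          seed = 1L, decisionThreshold = 0.5) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  if (is.null(featureNames)) {
    featureNames <- paste0("F", seq_len(ncol(X)))
    colnames(X) <- featureNames
  }
  X <- X[, featureNames, drop = FALSE]
  hp <- utils::modifyList(defaultHyperparams(), hyperparams)
  subsets <- makeBalancedSubsets(y, nSubsets, seed = seed)
  seeds <- .withSeed(seed, sample.int(2^31 - 1, nSubsets))
  members <- vector("list", nSubsets)
  ok <- logical(nSubsets)
  for (s in seq_len(nSubsets)) {
    idx <- subsets[[s]]$indices
    fit <- tryCatch(
      .fitMember(X[idx, , drop = FALSE], as.integer(y)[idx], classifier,
                 hp, seeds[s]),
      error = function(e) {
        warning("dropping ensemble member ", s, ": ",
                conditionMessage(e))
        NULL
      })
    members[[s]] <- fit
    ok[s] <- !is.null(fit)
  }
  if (sum(ok) < nSubsets / 2)
    stop("more than half the ensemble members failed to fit",
         call. = FALSE)
  new("BalancedEnsemble", members = members[ok],
      classifier = classifier, featureNames = featureNames,
      nSubsets = as.integer(nSubsets),
      decisionThreshold = decisionThreshold,
      seeds = as.integer(seeds[ok]))
}

#' Ensemble mutated-class probability
#'
#' The arithmetic mean of the member probabilities; column names of the
#' new data must match the model's feature list exactly and in order.
#'
#' @param model a \linkS4class{BalancedEnsemble}.
#' @param X numeric matrix of samples to score.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predictProbability <- function(model, X) {
  stopifnot(is(model, "BalancedEnsemble"))
  X <- as.matrix(X)
  if (!identical(colnames(X), model@featureNames)) {
    missing <- setdiff(model@featureNames, colnames(X))
    extra <- setdiff(colnames(X), model@featureNames)
    stop("feature columns do not match the model",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")),
         if (!length(missing) && !length(extra)) "; order differs",
         call. = FALSE)
  }
  probs <- vapply(model@members,
                  function(m) .memberProb(m, model@classifier, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}

#' @describeIn predictProbability class calls at the model's decision
#'   threshold (1 = mutated).
#' @export
predictClass <- function(model, X) {
  as.integer(predictProbability(model, X) >= model@decisionThreshold)
}

#' SMOTE minority oversampling (comparator)
#'
#' Synthetic minority samples are generated by uniform interpolation
#' between a minority sample and one of its k nearest minority neighbors
#' (Euclidean), until the class counts are equal.
#'
#' @param X numeric matrix.
#' @param y binary labels; the minority class is oversampled.
#' @param kNeighbors number of nearest neighbors, default 5; must be
#'   smaller than the minority count.
#' @param seed integer seed.
#' @return list with the augmented \code{X} and \code{y}.
#' @export
smoteOversample <- function(X, y, kNeighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  minLab <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  idxMin <- which(y == minLab)
  need <- abs(tab[["0"]] - tab[["1"]])
  if (need == 0L) return(list(X = X, y = y))
  if (kNeighbors >= length(idxMin))
    stop("kNeighbors must be smaller than the minority-class count",
         call. = FALSE)
  Xm <- X[idxMin, , drop = FALSE]
  dm <- as.matrix(dist(Xm))
  diag(dm) <- Inf
  nn <- t(apply(dm, 1, function(r) order(r)[seq_len(kNeighbors)]))
  .withSeed(seed, {
    base <- sample(seq_len(nrow(Xm)), need, replace = TRUE)
    pick <- nn[cbind(base, sample(seq_len(kNeighbors), need,
                                  replace = TRUE))]
    u <- runif(need)
    synth <- Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
    list(X = rbind(X, synth), y = c(y, rep(minLab, need)))
  })
}
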