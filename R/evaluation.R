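## Classification metrics, ROC/AUC by the rank (Mann-Whitney)
## formulation, and the DeLong placement-value variance for the AUC.

#' ROC curve with AUC (and optional DeLong CI)
#'
#' @slot thresholds numeric vector of score thresholds (decreasing).
#' @slot sensitivity numeric vector.
#' @slot fpr numeric vector (1 - specificity).
#' @slot auc numeric in [0, 1].
#' @slot aucSE numeric (NA until \code{\link{delongCI}} fills it).
#' @slot ciLow,ciHigh numeric CI bounds.
#' @slot level confidence level.
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 fpr = "numeric", auc = "numeric", aucSE = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 level = "numeric"))

setMethod("show", "ROCResult", function(object) {
  cat("ROC: AUC ", format(object@auc, digits = 4), sep = "")
  if (!is.na(object@aucSE))
    cat(" (SE ", format(object@aucSE, digits = 4), ", ",
        100 * object@level, "% CI ", format(object@ciLow, digits = 4),
        "-", format(object@ciHigh, digits = 4), ")", sep = "")
  cat("\n")
})

.checkScores <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("both classes must be present", call. = FALSE)
  labels
}

#' ROC curve and rank-based AUC
#'
#' AUC via the Mann-Whitney formulation with midrank tie correction (tied
#' positive/negative score pairs contribute 1/2); this equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric prediction scores (higher = more likely mutated).
#' @param labels binary labels (1 = mutated).
#' @return a \linkS4class{ROCResult} without SE/CI.
#' @export
rocAUC <- function(scores, labels) {
  labels <- .checkScores(scores, labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels == 1L] >= t),
                 numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t),
                numeric(1))
  new("ROCResult", thresholds = thr, sensitivity = sens, fpr = fpr,
      auc = auc, aucSE = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
      level = NA_real_)
}

#' DeLong variance and confidence interval for the AUC
#'
#' Placement values (structural components) are computed per sample with
#' the midrank tie convention; \eqn{var(AUC) = S_{10}/n_1 + S_{01}/n_0}
#' from their sample variances, and the CI is the normal approximation
#' \eqn{AUC \pm z \cdot SE} truncated to [0, 1].  Perfect separation gives
#' SE = 0 and a degenerate point CI, with a warning.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = mutated), at least two per class.
#' @param level confidence level, default 0.95.
#' @return a \linkS4class{ROCResult} with SE and CI filled in.
#' @export
delongCI <- function(scores, labels, level = 0.95) {
  labels <- .checkScores(scores, labels)
  if (min(table(labels)) < 2L)
    stop("DeLong needs at least two samples per class", call. = FALSE)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  n1 <- length(pos); n0 <- length(neg)
  ## placement of each positive among negatives and vice versa
  v10 <- vapply(pos, function(s) (sum(s > neg) + 0.5 * sum(s == neg)) / n0,
                numeric(1))
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / n1,
                numeric(1))
  roc <- rocAUC(scores, labels)
  v <- var(v10) / n1 + var(v01) / n0
  se <- sqrt(max(v, 0))
  if (se == 0)
    warning("zero DeLong variance (perfect separation); the CI ",
            "degenerates to a point")
  z <- qnorm(1 - (1 - level) / 2)
  new("ROCResult", thresholds = roc@thresholds,
      sensitivity = roc@sensitivity, fpr = roc@fpr, auc = roc@auc,
      aucSE = se,
      ciLow = max(0, roc@auc - z * se),
      ciHigh = min(1, roc@auc + z * se),
      level = level)
}

#' Confusion-count classification metrics
#'
#' Accuracy, sensitivity, specificity, precision and F1 from the confusion
#' counts, with the mutated class as positive.  A metric with a zero
#' denominator is reported as \code{NA} with a warning rather than 0.
#'
#' @param predictions binary class calls (1 = mutated).
#' @param labels binary reference labels.
#' @return named list: metrics plus counts \code{TP, FP, TN, FN}.
#' @export
classMetrics <- function(predictions, labels) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length", call. = FALSE)
  tp <- sum(predictions == 1L & labels == 1L)
  fp <- sum(predictions == 1L & labels == 0L)
  tn <- sum(predictions == 0L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA")
      NA_real_
    } else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0)
    NA_real_ else 2 * prec * sens / (prec + sens)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = sens,
       specificity = safe(tn, tn + fp, "specificity"),
       precision = prec,
       f1 = f1,
       TP = tp, FP = fp, TN = tn, FN = fn)
}
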