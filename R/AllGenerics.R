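#' Extract the patients-by-features matrix
#'
#' @param x a \linkS4class{RadiomicsFeatureSet}.
#' @return numeric matrix with patients as rows and features as columns.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "RadiomicsFeatureSet", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' IDH labels of a feature set
#'
#' @param x a \linkS4class{RadiomicsFeatureSet}.
#' @return integer vector named by patient: 1 = mutated, 0 = wild type.
#' @export
setGeneric("idhLabels", function(x) standardGeneric("idhLabels"))

#' @rdname idhLabels
#' @export
setMethod("idhLabels", "RadiomicsFeatureSet", function(x) {
  setNames(as.integer(SummarizedExperiment::colData(x)$IDH), colnames(x))
})

#' Features confirmed by a selection result
#'
#' For a \linkS4class{BorutaDecision}: the confirmed features.  For a
#' \linkS4class{SelectionFrequency}: features confirmed in at least
#' \code{thresholdFraction} of the balanced subsets; if none reaches the
#' threshold, the top \code{fallbackK} features by frequency (a warning is
#' attached when that fallback was needed at construction time).
#'
#' @param x a selection result.
#' @return character vector of feature names.
#' @export
setGeneric("relevantFeatures", function(x) standardGeneric("relevantFeatures"))

#' @rdname relevantFeatures
#' @export
setMethod("relevantFeatures", "BorutaDecision", function(x) {
  names(x@decisions)[x@decisions == "confirmed"]
})

#' @rdname relevantFeatures
#' @export
setMethod("relevantFeatures", "SelectionFrequency", function(x) {
  frac <- x@counts / x@nSubsets
  rel <- names(x@counts)[frac >= x@thresholdFraction]
  if (length(rel) == 0L) {
    k <- min(x@fallbackK, length(x@counts))
    rel <- names(sort(x@counts, decreasing = TRUE))[seq_len(k)]
  }
  rel
})

#' Selection frequencies as a fraction of subsets
#'
#' @param x a \linkS4class{SelectionFrequency}.
#' @return named numeric vector in [0, 1].
#' @export
setGeneric("selectionFraction", function(x) standardGeneric("selectionFraction"))

#' @rdname selectionFraction
#' @export
setMethod("selectionFraction", "SelectionFrequency", function(x) {
  x@counts / x@nSubsets
})
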