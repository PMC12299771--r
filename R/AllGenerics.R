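#' Accessors for package classes
#'
#' `featureValues()` returns the numeric sample-by-feature matrix,
#' `sampleLabels()` the aligned factor of class labels, `featureNames()` the
#' feature (column) names, `selectedFeatures()` the logical mask or the
#' 0-based indices (`indices = TRUE`) of a [FeatureMask-class], and
#' `trainReport()` the per-epoch training history of a [BiGRUModel-class].
#'
#' @param x an object of the documented class.
#' @param ... further arguments for methods.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x, ...) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x, ...) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures",
           function(x, ...) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("trainReport", function(x, ...) standardGeneric("trainReport"))

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureMatrix", function(x, ...) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("featureNames", "ScalerState", function(x, ...) x@featureNames)

#' @param indices logical; if `TRUE` return 0-based selected column indices
#'   instead of the logical mask.
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "FeatureMask", function(x, indices = FALSE, ...) {
  if (indices) which(x@selected) - 1L else x@selected
})

#' @rdname accessors
#' @export
setMethod("trainReport", "BiGRUModel", function(x, ...) x@report)

#' @describeIn FeatureMatrix dimensions (samples, features).
#' @param x a `FeatureMatrix`.
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  tab <- table(object@labels)
  cat(sprintf("FeatureMatrix: %d samples x %d features\n",
              nrow(object@values), ncol(object@values)))
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(object)
})

setMethod("show", "ScalerState", function(object) {
  cat(sprintf("ScalerState over %d features (%s)\n",
              length(object@featureNames), object@provenance))
  invisible(object)
})

setMethod("show", "FeatureMask", function(object) {
  cat(sprintf(
    "FeatureMask: %d / %d features selected\n  errorRate %.4f, sizeRatio %.4f, fitness %.4f (alpha = %.2f)\n",
    sum(object@selected), length(object@selected), object@errorRate,
    object@sizeRatio, object@fitness, object@alpha))
  invisible(object)
})

setMethod("show", "BiGRUModel", function(object) {
  cat(sprintf(
    "BiGRUModel: D = %d (chunks of %d), hidden = %d, pooling = %s\n  classes: %s\n",
    object@inputDim, object@chunk, object@hidden, object@pooling,
    paste(object@classLevels, collapse = ", ")))
  if (length(object@report$loss))
    cat(sprintf("  trained %d epochs, final loss %.4f, final accuracy %.4f\n",
                length(object@report$loss),
                tail(object@report$loss, 1), tail(object@report$accuracy, 1)))
  invisible(object)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport on %d samples, %d classes\n", object@n,
              nrow(object@confusion)))
  cat(sprintf("  multiclass accuracy: %.4f\n", object@accuracy))
  m <- object@macro
  cat(sprintf(
    "  macro: accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f  AUC %.4f\n",
    m["accuracy"], m["precision"], m["recall"], m["f1"], m["auc"]))
  invisible(object)
})
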