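#' @import methods
NULL

#' FeatureMatrix: a labeled sample-by-feature matrix
#'
#' The central data container of the package: a numeric matrix with one row
#' per molecule (sample) and one column per feature (fingerprint bit or
#' physical descriptor), carrying an aligned class label for every row.
#'
#' @slot values numeric matrix, `n` samples by `D` features; column names are
#'   the feature names.
#' @slot labels factor of length `n` with the class of each sample.
#'
#' @seealso [FeatureMatrix()], [featurizeTable()], [generateSynthetic()]
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", labels = "factor"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(object@values) < 1L || ncol(object@values) < 1L)
    msg <- c(msg, "'values' must have at least one row and one column")
  if (length(object@labels) != nrow(object@values))
    msg <- c(msg, sprintf("length of 'labels' (%d) must equal nrow(values) (%d)",
                          length(object@labels), nrow(object@values)))
  if (is.null(colnames(object@values)))
    msg <- c(msg, "'values' must have column (feature) names")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (samples by features). If it has no column
#'   names, names `bit_0000`, `bit_0001`, ... are generated.
#' @param labels character or factor vector of class labels, one per row.
#' @return A [FeatureMatrix-class] object.
#' @examples
#' fm <- FeatureMatrix(matrix(rnorm(20), 5, 4), rep(c("a", "b"), c(2, 3)))
#' dim(fm)
#' @export
FeatureMatrix <- function(values, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- defaultFeatureNames(ncol(values))
  new("FeatureMatrix", values = values, labels = as.factor(labels))
}

defaultFeatureNames <- function(D) {
  sprintf("bit_%04d", seq_len(D) - 1L)
}

#' ScalerState: learned preprocessing statistics
#'
#' Per-feature statistics learned on a training split only: the median used
#' for imputation, the 1st/99th-percentile caps, and the mean and
#' (population) standard deviation used for Z-scoring. The `provenance` tag
#' records which data the state was fit on so leakage can be audited.
#'
#' @slot median numeric, per-feature imputation value.
#' @slot capLow,capHigh numeric, lower/upper winsorization caps.
#' @slot center,scale numeric, Z-score mean and population sd (of the capped
#'   training values).
#' @slot featureNames character, feature names the state applies to.
#' @slot provenance character scalar describing the fitting data.
#' @export
setClass("ScalerState",
  representation(median = "numeric", capLow = "numeric", capHigh = "numeric",
                 center = "numeric", scale = "numeric",
                 featureNames = "character", provenance = "character"))

setValidity("ScalerState", function(object) {
  D <- length(object@featureNames)
  lens <- c(length(object@median), length(object@capLow),
            length(object@capHigh), length(object@center),
            length(object@scale))
  msg <- character()
  if (any(lens != D))
    msg <- c(msg, "all statistic vectors must match length(featureNames)")
  if (any(object@scale < 0))
    msg <- c(msg, "'scale' entries must be >= 0")
  if (any(object@capLow > object@capHigh))
    msg <- c(msg, "capLow must be <= capHigh for every feature")
  if (length(msg)) msg else TRUE
})

#' FeatureMask: a selected feature subset with its fitness decomposition
#'
#' Result of the Bald Eagle Search wrapper: a boolean mask over the feature
#' space together with the surrogate cross-validated error rate on the
#' selected columns, the subset-size ratio |R|/|C|, and the combined wrapper
#' fitness `alpha * error + (1 - alpha) * |R|/|C|`.
#'
#' @slot selected logical vector over features (at least one `TRUE`).
#' @slot errorRate numeric scalar, surrogate CV error on selected columns.
#' @slot sizeRatio numeric scalar, selected fraction of all features.
#' @slot fitness numeric scalar, combined wrapper objective.
#' @slot alpha numeric scalar, error weight used in the combination.
#' @export
setClass("FeatureMask",
  representation(selected = "logical", errorRate = "numeric",
                 sizeRatio = "numeric", fitness = "numeric",
                 alpha = "numeric"))

setValidity("FeatureMask", function(object) {
  msg <- character()
  # An empty mask is only representable as the +Inf sentinel (never a
  # usable selection result).
  if (!any(object@selected) && is.finite(object@fitness))
    msg <- c(msg, "at least one feature must be selected")
  if (length(object@alpha) == 1 && length(object@fitness) == 1 &&
      is.finite(object@fitness)) {
    want <- object@alpha * object@errorRate +
      (1 - object@alpha) * object@sizeRatio
    if (abs(want - object@fitness) > 1e-9)
      msg <- c(msg, "fitness must equal alpha*errorRate + (1-alpha)*sizeRatio")
  }
  if (length(msg)) msg else TRUE
})

#' BiGRUModel: a trained bidirectional GRU classifier
#'
#' Holds the gate weights of the forward and backward GRU cells, the output
#' projection, the input shaping specification (feature count `inputDim` and
#' chunk width `chunk` used to fold a flat feature vector into a sequence),
#' the class ordering, and the training hyperparameters and report.
#'
#' Each cell parameter list has elements `Wr`, `Wz`, `Wh` (H x (H+F)
#' matrices acting on the concatenation of previous hidden state and current
#' input chunk) and `br`, `bz`, `bh` (length-H biases).
#'
#' @slot forward,backward list of GRU cell parameters (see above).
#' @slot Wout numeric matrix, output projection (classes x pooled-state).
#' @slot bout numeric, output bias.
#' @slot hidden integer, hidden size H.
#' @slot chunk integer, input chunk width F.
#' @slot inputDim integer, flat feature dimension D the model was trained on.
#' @slot classLevels character, class names in model (lexicographic) order.
#' @slot pooling character, "concat" or "mean" combination of directions.
#' @slot hyper list of training hyperparameters (learning rate, batch size,
#'   dropout, epochs, seed).
#' @slot report list; per-epoch training loss and accuracy.
#' @export
setClass("BiGRUModel",
  representation(forward = "list", backward = "list",
                 Wout = "matrix", bout = "numeric",
                 hidden = "integer", chunk = "integer", inputDim = "integer",
                 classLevels = "character", pooling = "character",
                 hyper = "list", report = "list"))

setValidity("BiGRUModel", function(object) {
  msg <- character()
  H <- object@hidden
  Fw <- object@chunk
  for (side in c("forward", "backward")) {
    p <- slot(object, side)
    need <- c("Wr", "Wz", "Wh", "br", "bz", "bh")
    if (!all(need %in% names(p))) {
      msg <- c(msg, sprintf("'%s' cell must contain %s", side,
                            paste(need, collapse = ", ")))
      next
    }
    for (w in c("Wr", "Wz", "Wh"))
      if (!all(dim(p[[w]]) == c(H, H + Fw)))
        msg <- c(msg, sprintf("%s$%s must be %d x %d", side, w, H, H + Fw))
    for (b in c("br", "bz", "bh"))
      if (length(p[[b]]) != H)
        msg <- c(msg, sprintf("%s$%s must have length %d", side, b, H))
  }
  if (length(object@classLevels) < 2L)
    msg <- c(msg, "model must have at least 2 classes")
  if (!object@pooling %in% c("concat", "mean"))
    msg <- c(msg, "pooling must be 'concat' or 'mean'")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: per-class and macro classification metrics
#'
#' The evaluation battery: a k x k confusion matrix (rows = true class),
#' per-class one-vs-rest accuracy, precision, recall, F1 and AUC, their
#' unweighted macro averages, and the plain multiclass accuracy.
#'
#' @slot confusion numeric matrix, k x k, rows are true classes.
#' @slot perClass data.frame with one row per class and columns
#'   `accuracy`, `precision`, `recall`, `f1`, `auc` (fractions in `[0,1]`).
#' @slot macro named numeric with the unweighted means of the per-class
#'   columns.
#' @slot accuracy numeric scalar, plain multiclass accuracy
#'   (trace/total of the confusion matrix).
#' @slot n integer, number of evaluated samples.
#' @export
setClass("MetricsReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 macro = "numeric", accuracy = "numeric", n = "integer"))

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  if (sum(object@confusion) != object@n)
    msg <- c(msg, "confusion matrix entries must sum to n")
  rs <- rowSums(object@confusion)
  nz <- rs > 0
  rec <- diag(object@confusion)[nz] / rs[nz]
  if (any(abs(rec - object@perClass$recall[nz]) > 1e-9))
    msg <- c(msg, "per-class recall must equal diagonal/row-sum")
  if (length(msg)) msg else TRUE
})
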