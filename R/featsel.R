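#' Wrapper feature-selection control parameters
#'
#' Settings for the wrapper objective used by [selectFeatures()]:
#' `fitness = alpha * errorRate + (1 - alpha) * |R|/|C|`, where the error
#' rate is the stratified cross-validated error of a surrogate classifier
#' on the selected columns and `|R|/|C|` is the selected fraction of all
#' features.
#'
#' @param alpha error-rate weight in `[0, 1]` (default 0.9); the subset-size
#'   weight is `1 - alpha`.
#' @param threshold binarization threshold on the continuous eagle position
#'   (default 0.5): coordinate > threshold selects the feature.
#' @param folds stratified CV folds for the surrogate (default 3).
#' @param k neighbours of the k-NN surrogate (default 1).
#' @param evaluator optional custom surrogate: a
#'   `function(X, y, foldIds)` returning an error rate in `[0, 1]`
#'   (e.g. a BiGRU-based evaluator for final verification runs). `NULL`
#'   uses the k-NN surrogate.
#' @return A list of class `fsControl`.
#' @export
fsControl <- function(alpha = 0.9, threshold = 0.5, folds = 3L, k = 1L,
                      evaluator = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  folds <- as.integer(folds); k <- as.integer(k)
  if (folds < 2L) stop("folds must be >= 2")
  if (k < 1L) stop("k must be >= 1")
  if (!is.null(evaluator) && !is.function(evaluator))
    stop("evaluator must be a function or NULL")
  structure(list(alpha = alpha, threshold = threshold, folds = folds, k = k,
                 evaluator = evaluator),
            class = "fsControl")
}

# Pooled k-NN misclassification rate over precomputed fold ids.
# Distances are squared Euclidean, computed via the Gram matrix.
knnErrorWithFolds <- function(X, y, foldIds, k = 1L) {
  y <- as.factor(y)
  n <- nrow(X)
  G <- tcrossprod(X)
  sq <- diag(G)
  wrong <- 0L
  for (f in sort(unique(foldIds))) {
    te <- which(foldIds == f)
    tr <- which(foldIds != f)
    d2 <- outer(sq[te], sq[tr], "+") - 2 * G[te, tr, drop = FALSE]
    if (k == 1L) {
      nn <- max.col(-d2, ties.method = "first")
      pred <- y[tr][nn]
    } else {
      pred <- factor(apply(d2, 1L, function(row) {
        nb <- y[tr][order(row)[seq_len(k)]]
        names(which.max(table(nb)))
      }), levels = levels(y))
    }
    wrong <- wrong + sum(pred != y[te])
  }
  wrong / n
}

#' Stratified cross-validated k-NN error
#'
#' The default surrogate of the feature-selection wrapper: pooled
#' misclassification rate of a k-nearest-neighbour classifier under
#' stratified cross-validation. Fold assignment is drawn under `seed`
#' without disturbing the caller's RNG state.
#'
#' @param X numeric matrix (samples by features).
#' @param y class labels aligned with rows of `X`.
#' @param folds number of stratified folds (default 3).
#' @param k neighbours (default 1).
#' @param seed integer seed for the fold assignment.
#' @return Error rate in `[0, 1]`.
#' @export
knnCvError <- function(X, y, folds = 3L, k = 1L, seed = 1L) {
  foldIds <- withLocalSeed(seed, stratifiedFolds(y, folds))
  knnErrorWithFolds(X, y, foldIds, k = k)
}

#' Binarize a continuous optimizer position into a feature mask
#'
#' The transfer rule of the wrapper: coordinate strictly greater than
#' `threshold` selects the feature.
#'
#' @param position numeric vector in `[0, 1]^D`.
#' @param threshold selection threshold (default 0.5).
#' @return Logical mask of `length(position)`.
#' @examples
#' binarizePosition(c(0.7, 0.3, 0.51))  # TRUE FALSE TRUE
#' @export
binarizePosition <- function(position, threshold = 0.5) {
  position > threshold
}

#' Wrapper fitness of a feature mask
#'
#' Scores a boolean feature mask with the wrapper objective
#' `alpha * errorRate + (1 - alpha) * |R|/|C|`. The empty mask is never
#' evaluated: it receives the `+Inf` sentinel so greedy optimizers discard
#' it.
#'
#' @param mask logical vector over the columns of `X`.
#' @param X preprocessed numeric feature matrix.
#' @param y aligned class labels.
#' @param control an [fsControl()].
#' @param foldIds optional precomputed fold assignment (from
#'   [stratifiedFolds] semantics); when `NULL`, folds are drawn under
#'   `seed`.
#' @param seed fold-assignment seed when `foldIds` is `NULL`.
#' @return A [FeatureMask-class] with the fitness decomposition.
#' @examples
#' X <- matrix(rnorm(40), 20, 2); y <- rep(c("a", "b"), 10)
#' fsFitness(c(TRUE, FALSE), X, y, fsControl())
#' @export
fsFitness <- function(mask, X, y, control = fsControl(), foldIds = NULL,
                      seed = 1L) {
  stopifnot(inherits(control, "fsControl"))
  mask <- as.logical(mask)
  if (length(mask) != ncol(X)) stop("mask length must equal ncol(X)")
  D <- length(mask)
  if (!any(mask))
    return(new("FeatureMask", selected = mask, errorRate = NA_real_,
               sizeRatio = 0, fitness = Inf, alpha = control$alpha))
  if (is.null(foldIds))
    foldIds <- withLocalSeed(seed, stratifiedFolds(y, control$folds))
  Xs <- X[, mask, drop = FALSE]
  gamma <- if (is.null(control$evaluator))
    knnErrorWithFolds(Xs, y, foldIds, k = control$k)
  else control$evaluator(Xs, y, foldIds)
  ratio <- sum(mask) / D
  new("FeatureMask", selected = mask, errorRate = gamma, sizeRatio = ratio,
      fitness = control$alpha * gamma + (1 - control$alpha) * ratio,
      alpha = control$alpha)
}

#' Select features with the Bald Eagle Search wrapper
#'
#' Runs [besMinimize()] over the unit hypercube `[0,1]^D`; a continuous
#' position is binarized to a feature mask by thresholding each coordinate
#' at `control$threshold`, and the mask is scored with [fsFitness()]. The
#' surrogate's CV fold assignment is drawn once per run so all masks are
#' scored on identical folds. Deterministic under `seed`.
#'
#' @param fm a preprocessed [FeatureMatrix-class] (training split only).
#' @param besCtrl a [besControl()].
#' @param control an [fsControl()].
#' @param seed integer seed for folds and the optimizer.
#' @return A [FeatureMask-class] for the best mask found; the best-so-far
#'   fitness trace is attached as `attr(, "trace")`.
#' @export
selectFeatures <- function(fm, besCtrl = besControl(), control = fsControl(),
                           seed = 1L) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- featureValues(fm)
  y <- sampleLabels(fm)
  D <- ncol(X)
  if (D == 0L) stop("no features to select from")
  foldIds <- withLocalSeed(stageSeed(seed, "fs"), stratifiedFolds(y, control$folds))
  objective <- function(pos) {
    mask <- binarizePosition(pos, control$threshold)
    if (!any(mask)) return(.Machine$double.xmax)  # sentinel, never evaluated
    fsFitness(mask, X, y, control, foldIds = foldIds)@fitness
  }
  out <- besMinimize(objective, dim = D, lower = 0, upper = 1,
                     control = besCtrl, seed = seed)
  best <- fsFitness(binarizePosition(out$best, control$threshold), X, y,
                    control, foldIds = foldIds)
  attr(best, "trace") <- out$trace
  best
}

#' Serialize a FeatureMask
#'
#' Writes the selected column indices (0-based, newline-delimited) to
#' `path` and the fitness decomposition to a JSON sidecar `<path>.json`;
#' `readFeatureMask()` reads the pair back.
#'
#' @param mask a [FeatureMask-class].
#' @param path output path for the index list.
#' @return `writeFeatureMask()` returns `path` invisibly; `readFeatureMask()`
#'   a [FeatureMask-class].
#' @export
writeFeatureMask <- function(mask, path) {
  stopifnot(is(mask, "FeatureMask"))
  writeLines(as.character(selectedFeatures(mask, indices = TRUE)), path)
  jsonWrite(list(D = length(mask@selected), errorRate = mask@errorRate,
                 sizeRatio = mask@sizeRatio, fitness = mask@fitness,
                 alpha = mask@alpha), paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeFeatureMask
#' @export
readFeatureMask <- function(path) {
  idx0 <- as.integer(readLines(path))
  meta <- jsonRead(paste0(path, ".json"))
  sel <- rep(FALSE, meta$D)
  sel[idx0 + 1L] <- TRUE
  new("FeatureMask", selected = sel, errorRate = as.numeric(meta$errorRate),
      sizeRatio = as.numeric(meta$sizeRatio),
      fitness = as.numeric(meta$fitness), alpha = as.numeric(meta$alpha))
}
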