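# Percentile with linear interpolation between order statistics
# (quantile type 7), computed on imputed values.
linearQuantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

#' Fit the preprocessing state on a training split
#'
#' Learns, per feature and in this order: the median used to impute missing
#' values, the 1st/99th-percentile caps computed on the imputed values, and
#' the mean and population standard deviation of the capped values used for
#' Z-scoring. Statistics are learned on the training split only; the
#' returned state carries a provenance tag for leakage audits.
#'
#' @param train a [FeatureMatrix-class] (the training split).
#' @param probs lower/upper capping percentiles (default `c(0.01, 0.99)`).
#' @param provenance free-text tag recording what the state was fit on.
#' @return A [ScalerState-class].
#' @examples
#' fm <- FeatureMatrix(matrix(rnorm(300), 100, 3), rep("a", 100))
#' s <- fitPreprocessor(fm)
#' @export
fitPreprocessor <- function(train, probs = c(0.01, 0.99),
                            provenance = "training split") {
  stopifnot(is(train, "FeatureMatrix"))
  X <- featureValues(train)
  D <- ncol(X)
  med <- capLow <- capHigh <- ctr <- scl <- numeric(D)
  for (j in seq_len(D)) {
    x <- X[, j]
    if (all(is.na(x)))
      stop("feature '", colnames(X)[j], "' is entirely missing")
    m <- stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- m
    lo <- linearQuantile(x, probs[1])
    hi <- linearQuantile(x, probs[2])
    xc <- clipTo(x, lo, hi)
    mu <- mean(xc)
    sd0 <- sqrt(mean((xc - mu)^2))  # population sd
    med[j] <- m; capLow[j] <- lo; capHigh[j] <- hi
    ctr[j] <- mu; scl[j] <- sd0
  }
  new("ScalerState", median = med, capLow = capLow, capHigh = capHigh,
      center = ctr, scale = scl, featureNames = colnames(X),
      provenance = provenance)
}

#' Apply a fitted preprocessing state
#'
#' Imputes missing values with the stored medians, caps at the stored
#' percentile bounds, and Z-scores with the stored mean and population
#' standard deviation. Constant features (stored sd of 0) map to 0 rather
#' than NaN.
#'
#' @param fm a [FeatureMatrix-class] whose features match the state.
#' @param state a [ScalerState-class] from [fitPreprocessor()].
#' @return A [FeatureMatrix-class] of standardized values (no NaN).
#' @export
applyPreprocessor <- function(fm, state) {
  stopifnot(is(fm, "FeatureMatrix"), is(state, "ScalerState"))
  X <- featureValues(fm)
  if (ncol(X) != length(state@featureNames))
    stop(sprintf("feature dimension mismatch: data has %d, state has %d",
                 ncol(X), length(state@featureNames)))
  if (!identical(colnames(X), state@featureNames))
    stop("feature names do not match the scaler state")
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[is.na(x)] <- state@median[j]
    x <- clipTo(x, state@capLow[j], state@capHigh[j])
    s <- state@scale[j]
    X[, j] <- if (s > 0) (x - state@center[j]) / s else 0
  }
  FeatureMatrix(X, sampleLabels(fm))
}

#' Serialize a ScalerState to and from JSON
#'
#' @param state a [ScalerState-class].
#' @param path JSON file path.
#' @return `writeScaler()` returns `path` invisibly; `readScaler()` returns
#'   a [ScalerState-class].
#' @export
writeScaler <- function(state, path) {
  stopifnot(is(state, "ScalerState"))
  jsonWrite(list(median = state@median, capLow = state@capLow,
                 capHigh = state@capHigh, center = state@center,
                 scale = state@scale, featureNames = state@featureNames,
                 provenance = state@provenance), path)
  invisible(path)
}

#' @rdname writeScaler
#' @export
readScaler <- function(path) {
  x <- jsonRead(path)
  new("ScalerState", median = as.numeric(x$median),
      capLow = as.numeric(x$capLow), capHigh = as.numeric(x$capHigh),
      center = as.numeric(x$center), scale = as.numeric(x$scale),
      featureNames = as.character(x$featureNames),
      provenance = as.character(x$provenance))
}
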