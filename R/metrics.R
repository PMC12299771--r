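#' Stratified train/test split
#'
#' Splits sample indices into disjoint, exhaustive train and test sets
#' preserving per-class proportions to within one sample. Per-class train
#' counts are `floor(n_c * trainFrac)` with the remaining
#' `round(n * trainFrac) - sum(floor)` seats distributed by largest
#' fractional remainder (ties broken by class order). Deterministic under
#' `seed`.
#'
#' @param y class labels (or a [FeatureMatrix-class], whose labels are
#'   used).
#' @param trainFrac training fraction (default 0.7).
#' @param seed integer seed for the within-class shuffles.
#' @return list with integer index vectors `train` and `test`.
#' @examples
#' sp <- stratifiedSplit(rep(c("a", "b"), c(5, 5)), 0.7, seed = 1)
#' length(sp$train)  # 7
#' @export
stratifiedSplit <- function(y, trainFrac = 0.7, seed = 1L) {
  if (is(y, "FeatureMatrix")) y <- sampleLabels(y)
  y <- as.factor(droplevels(as.factor(y)))
  counts <- table(y)
  if (any(counts < 2L))
    stop("every class needs >= 2 members; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  n <- length(y)
  target <- round(n * trainFrac)
  base <- floor(as.numeric(counts) * trainFrac)
  rem <- as.numeric(counts) * trainFrac - base
  extra <- target - sum(base)
  take <- base
  if (extra > 0) {
    ord <- order(-rem, seq_along(rem))
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
  }
  withLocalSeed(seed, {
    trainIdx <- integer(0)
    for (ci in seq_along(levels(y))) {
      idx <- which(y == levels(y)[ci])
      idx <- idx[sample.int(length(idx))]
      trainIdx <- c(trainIdx, idx[seq_len(take[ci])])
    }
    list(train = sort(trainIdx), test = sort(setdiff(seq_len(n), trainIdx)))
  })
}

# One-vs-rest AUC with midrank tie handling (Mann-Whitney statistic).
midrankAuc <- function(score, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs both positive and negative samples")
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Per-class and macro classification metrics
#'
#' Builds the full evaluation battery from true labels, predicted labels
#' and predicted class probabilities: the k x k confusion matrix (rows =
#' true class) and, per class in one-vs-rest terms, accuracy
#' `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic
#' mean) and AUC (midrank one-vs-rest on the class's probability column),
#' plus their unweighted macro averages and the plain multiclass accuracy.
#' Precision and F1 fall back to 0 when their denominator is 0; a class
#' absent from `yTrue` is an error (its recall is undefined).
#'
#' @param yTrue true labels.
#' @param yPred predicted labels.
#' @param proba `n x k` probability matrix with class-name columns covering
#'   all observed classes; rows must sum to 1 (tolerance 1e-6).
#' @return A [MetricsReport-class].
#' @examples
#' yT <- c("a", "a", "b", "b"); yP <- c("a", "b", "b", "b")
#' pr <- matrix(c(.9, .4, .2, .1, .1, .6, .8, .9), 4, 2,
#'              dimnames = list(NULL, c("a", "b")))
#' computeMetrics(yT, yP, pr)
#' @export
computeMetrics <- function(yTrue, yPred, proba) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("yTrue and yPred length mismatch")
  n <- length(yTrue)
  classes <- sort(unique(c(yTrue, yPred, colnames(proba))))
  missing <- setdiff(classes, unique(yTrue))
  if (length(missing))
    stop("class absent from yTrue (recall undefined): ",
         paste(missing, collapse = ", "))
  if (nrow(proba) != n || !all(classes %in% colnames(proba)))
    stop("proba must be n x k with columns for all classes")
  if (any(abs(rowSums(proba) - 1) > 1e-6))
    stop("proba rows must sum to 1")
  k <- length(classes)
  conf <- matrix(0L, k, k, dimnames = list(true = classes, pred = classes))
  for (i in seq_len(n))
    conf[yTrue[i], yPred[i]] <- conf[yTrue[i], yPred[i]] + 1L
  per <- data.frame(accuracy = numeric(k), precision = numeric(k),
                    recall = numeric(k), f1 = numeric(k), auc = numeric(k),
                    row.names = classes)
  for (ci in seq_len(k)) {
    tp <- conf[ci, ci]
    fp <- sum(conf[-ci, ci])
    fn <- sum(conf[ci, -ci])
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    per$accuracy[ci] <- (tp + tn) / n
    per$precision[ci] <- prec
    per$recall[ci] <- rec
    per$f1[ci] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per$auc[ci] <- midrankAuc(proba[, classes[ci]], yTrue == classes[ci])
  }
  macro <- vapply(per, mean, numeric(1))
  new("MetricsReport", confusion = conf, perClass = per, macro = macro,
      accuracy = sum(diag(conf)) / n, n = as.integer(n))
}

#' Tabulate macro metrics across runs
#'
#' Aligns the macro metrics (and plain multiclass accuracy) of several
#' [MetricsReport-class] objects into one comparison table.
#'
#' @param reports list of [MetricsReport-class] objects.
#' @param labels character run labels, one per report.
#' @param percent report values as percentages rounded to 2 decimals.
#' @return data.frame with one row per run.
#' @export
compareRuns <- function(reports, labels = NULL, percent = FALSE) {
  if (!length(reports)) stop("at least one report is required")
  if (is.null(labels)) labels <- paste0("run", seq_along(reports))
  stopifnot(length(labels) == length(reports))
  rows <- lapply(reports, function(r) {
    stopifnot(is(r, "MetricsReport"))
    c(multiclassAccuracy = r@accuracy, r@macro)
  })
  df <- data.frame(run = labels, do.call(rbind, rows),
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df) <- c("run", "multiclassAccuracy", "macroAccuracy",
                 "macroPrecision", "macroRecall", "macroF1", "macroAUC")
  if (percent)
    df[-1] <- lapply(df[-1], function(x) round(100 * x, 2))
  df
}

#' Serialize a MetricsReport
#'
#' `writeMetrics()` writes the full report (confusion matrix, per-class and
#' macro metrics, multiclass accuracy, n) to JSON;
#' `writeConfusionCsv()` writes the confusion matrix alone as CSV.
#'
#' @param report a [MetricsReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  jsonWrite(list(
    n = report@n,
    classes = rownames(report@confusion),
    confusion = apply(report@confusion, 1L, as.integer, simplify = FALSE),
    perClass = cbind(class = rownames(report@perClass), report@perClass),
    macro = as.list(report@macro),
    multiclassAccuracy = report@accuracy), path)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
writeConfusionCsv <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  utils::write.csv(as.data.frame(report@confusion), path, row.names = TRUE)
  invisible(path)
}
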