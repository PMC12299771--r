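# Deterministic polynomial hash of a string (mod 2^31 - 1); used to
# fingerprint resolved configurations in run provenance records.
configHash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' Bundles every stage's settings for [runPipeline()]: the data source
#' (either a molecule/feature CSV or a [syntheticSpec()]), the fingerprint
#' settings, the train fraction, stage toggles for feature selection and
#' tuning, the optimizer controls, the fallback BiGRU settings used when
#' tuning is off, and one master seed from which all per-stage seeds are
#' derived deterministically.
#'
#' @param input path to an input CSV (`smiles,label` columns, or a dense
#'   feature CSV with a `label` column), or `NULL` to generate data from
#'   `synthetic`.
#' @param synthetic a [syntheticSpec()] used when `input` is `NULL`.
#' @param outDir output directory for run artifacts.
#' @param fingerprint a [fingerprintConfig()] (used for SMILES input).
#' @param trainFrac stratified train fraction (default 0.7).
#' @param featureSelection,tune logical stage toggles.
#' @param besCtrl,fsCtrl,zoaCtrl,space optimizer controls and tuning space.
#' @param valFrac fraction of the training portion carved out as the
#'   tuner's internal validation split (default 0.2); the held-out test
#'   split is never used for tuning.
#' @param tuneSubsample cap on the inner-training size used to score
#'   tuning candidates (default 400); the winning configuration is
#'   retrained on the full training portion.
#' @param bigru named list of fallback BiGRU settings (`hidden`, `chunk`,
#'   `learningRate`, `batchSize`, `dropout`, `epochs`, `pooling`).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(input = NULL, synthetic = NULL,
                           outDir = tempfile("polygru_run_"),
                           fingerprint = fingerprintConfig(),
                           trainFrac = 0.7,
                           featureSelection = TRUE, tune = TRUE,
                           besCtrl = besControl(N = 15L, maxIter = 12L),
                           fsCtrl = fsControl(),
                           zoaCtrl = zoaControl(N = 4L, maxIter = 2L),
                           space = hyperparameterSpace(),
                           valFrac = 0.2, tuneSubsample = 400L,
                           bigru = list(), seed = 1L) {
  if (is.null(input) && is.null(synthetic))
    stop("provide either 'input' or 'synthetic'")
  defaults <- list(hidden = 32L, chunk = 16L, learningRate = 1e-3,
                   batchSize = 32L, dropout = 0.2, epochs = 40L,
                   pooling = "concat")
  bigru <- utils::modifyList(defaults, bigru)
  structure(list(input = input, synthetic = synthetic, outDir = outDir,
                 fingerprint = fingerprint, trainFrac = trainFrac,
                 featureSelection = isTRUE(featureSelection),
                 tune = isTRUE(tune), besCtrl = besCtrl, fsCtrl = fsCtrl,
                 zoaCtrl = zoaCtrl, space = space, valFrac = valFrac,
                 tuneSubsample = as.integer(tuneSubsample), bigru = bigru,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

maskFeatureMatrix <- function(fm, mask) {
  keep <- selectedFeatures(mask)
  FeatureMatrix(featureValues(fm)[, keep, drop = FALSE], sampleLabels(fm))
}

# Serializable snapshot of a resolved configuration (functions dropped).
configSnapshot <- function(cfg) {
  snap <- cfg
  snap$fsCtrl$evaluator <- NULL
  lapply(snap, function(x) if (is.list(x)) unclass(x) else x)
}

#' Run the full classification pipeline
#'
#' Executes the stages in order: data loading or synthesis, stratified
#' 70:30 split, preprocessing fit on the training split only, Bald Eagle
#' Search feature selection on the training split, Zebra Optimization
#' Algorithm hyperparameter tuning on an internal train/validation split
#' carved from the training portion, final BiGRU training, and evaluation
#' on the untouched test split. All artifacts (resolved config snapshot
#' with per-stage seeds and a config hash, scaler state, feature mask,
#' model archive, metrics report, confusion matrix, optimizer traces, log)
#' are written under `cfg$outDir`. A rerun with the identical
#' configuration reproduces the metrics report byte-for-byte.
#'
#' @param cfg a [pipelineConfig()].
#' @return Invisibly, a list with `outDir`, `model`, `scaler`, `mask`,
#'   `metrics`, `tuned` (tuning result or `NULL`) and `split`.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outDir, "log.txt")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  say <- function(...) writeLines(sprintf(...), logCon)

  # -- data -----------------------------------------------------------
  if (!is.null(cfg$input)) {
    header <- names(utils::read.csv(cfg$input, nrows = 1L))
    if ("smiles" %in% header) {
      tab <- readMoleculeCsv(cfg$input)
      fm <- featurizeTable(tab$smiles, tab$label, cfg$fingerprint)
      say("featurize: %d molecules -> %d bits", nrow(tab), ncol(fm))
    } else {
      fm <- readFeatureCsv(cfg$input)
      say("load: %d x %d feature matrix from %s", nrow(fm), ncol(fm),
          cfg$input)
    }
  } else {
    gen <- generateSynthetic(cfg$synthetic, seed = stageSeed(cfg$seed, "data"))
    fm <- gen$fm
    say("simulate: %d x %d (%s mode, %d informative)", nrow(fm), ncol(fm),
        cfg$synthetic$mode, cfg$synthetic$nInformative)
  }

  # -- split + preprocessing -----------------------------------------
  split <- stratifiedSplit(sampleLabels(fm), cfg$trainFrac,
                           seed = stageSeed(cfg$seed, "split"))
  X <- featureValues(fm); y <- sampleLabels(fm)
  trainFM <- FeatureMatrix(X[split$train, , drop = FALSE], y[split$train])
  testFM <- FeatureMatrix(X[split$test, , drop = FALSE], y[split$test])
  scaler <- fitPreprocessor(trainFM, provenance = sprintf(
    "training split (%d rows, master seed %d)", length(split$train),
    cfg$seed))
  trainFM <- applyPreprocessor(trainFM, scaler)
  testFM <- applyPreprocessor(testFM, scaler)
  writeScaler(scaler, file.path(cfg$outDir, "scaler.json"))
  say("preprocess: fitted on %d training rows", length(split$train))

  # -- feature selection ---------------------------------------------
  if (cfg$featureSelection) {
    mask <- selectFeatures(trainFM, cfg$besCtrl, cfg$fsCtrl,
                           seed = stageSeed(cfg$seed, "fs"))
    tr <- attr(mask, "trace")
    utils::write.csv(data.frame(iteration = seq_along(tr) - 1L, best = tr),
                     file.path(cfg$outDir, "fs_trace.csv"),
                     row.names = FALSE)
    say("select-features: %d / %d kept (error %.4f, fitness %.4f)",
        sum(selectedFeatures(mask)), ncol(trainFM), mask@errorRate,
        mask@fitness)
  } else {
    mask <- new("FeatureMask", selected = rep(TRUE, ncol(trainFM)),
                errorRate = NA_real_, sizeRatio = 1, fitness = NA_real_,
                alpha = cfg$fsCtrl$alpha)
    say("select-features: skipped (all %d features kept)", ncol(trainFM))
  }
  writeFeatureMask(mask, file.path(cfg$outDir, "feature_mask.txt"))
  trainMasked <- maskFeatureMatrix(trainFM, mask)
  testMasked <- maskFeatureMatrix(testFM, mask)

  # -- hyperparameter tuning -----------------------------------------
  bigruArgs <- cfg$bigru
  tuned <- NULL
  if (cfg$tune) {
    inner <- stratifiedSplit(sampleLabels(trainMasked), 1 - cfg$valFrac,
                             seed = stageSeed(cfg$seed, "tune"))
    Xtr <- featureValues(trainMasked); ytr <- sampleLabels(trainMasked)
    innerTrain <- inner$train
    if (length(innerTrain) > cfg$tuneSubsample) {
      sub <- stratifiedSplit(ytr[innerTrain],
                             cfg$tuneSubsample / length(innerTrain),
                             seed = stageSeed(cfg$seed, "tune"))
      innerTrain <- innerTrain[sub$train]
    }
    tuned <- tuneBiGRU(Xtr[innerTrain, , drop = FALSE], ytr[innerTrain],
                       Xtr[inner$test, , drop = FALSE], ytr[inner$test],
                       control = cfg$zoaCtrl, space = cfg$space,
                       chunk = bigruArgs$chunk, pooling = bigruArgs$pooling,
                       seed = stageSeed(cfg$seed, "tune"))
    utils::write.csv(data.frame(iteration = seq_along(tuned$trace) - 1L,
                                best = tuned$trace),
                     file.path(cfg$outDir, "tune_trace.csv"),
                     row.names = FALSE)
    bigruArgs$hidden <- tuned$best$gruUnits
    bigruArgs$learningRate <- tuned$best$learningRate
    bigruArgs$batchSize <- tuned$best$batchSize
    bigruArgs$dropout <- tuned$best$dropout
    bigruArgs$epochs <- tuned$best$epochs
    say("tune: best val error %.2f%% (lr %.5f, units %d, batch %d, dropout %.3f, epochs %d)",
        tuned$error, tuned$best$learningRate, tuned$best$gruUnits,
        tuned$best$batchSize, tuned$best$dropout, tuned$best$epochs)
  } else {
    say("tune: skipped (using configured BiGRU settings)")
  }

  # -- final training + evaluation -----------------------------------
  model <- trainBiGRU(trainMasked, hidden = bigruArgs$hidden,
                      chunk = bigruArgs$chunk,
                      learningRate = bigruArgs$learningRate,
                      batchSize = bigruArgs$batchSize,
                      dropout = bigruArgs$dropout,
                      epochs = bigruArgs$epochs,
                      pooling = bigruArgs$pooling,
                      seed = stageSeed(cfg$seed, "train"))
  trep <- trainReport(model)
  say("train: %d epochs, final loss %.4f, final training accuracy %.4f",
      length(trep$loss), trep$loss[length(trep$loss)],
      trep$accuracy[length(trep$accuracy)])
  proba <- predictProba(model, testMasked)
  pred <- model@classLevels[max.col(proba, ties.method = "first")]
  metrics <- computeMetrics(as.character(sampleLabels(testMasked)), pred,
                            proba)
  writeMetrics(metrics, file.path(cfg$outDir, "metrics.json"))
  writeConfusionCsv(metrics, file.path(cfg$outDir, "confusion.csv"))
  say("evaluate: multiclass accuracy %.4f, macro F1 %.4f on %d test rows",
      metrics@accuracy, metrics@macro[["f1"]], metrics@n)

  snap <- configSnapshot(cfg)
  snap$stageSeeds <- lapply(
    c(split = "split", fs = "fs", tune = "tune", train = "train",
      data = "data"),
    function(s) stageSeed(cfg$seed, s))
  snap$configHash <- configHash(jsonlite::toJSON(snap, auto_unbox = TRUE,
                                                 digits = NA))
  jsonWrite(snap, file.path(cfg$outDir, "config.json"))
  saveModelArchive(model, file.path(cfg$outDir, "model.json"),
                   scaler = scaler, mask = mask,
                   fingerprint = if (!is.null(cfg$input))
                     cfg$fingerprint else NULL)
  invisible(list(outDir = cfg$outDir, model = model, scaler = scaler,
                 mask = mask, metrics = metrics, tuned = tuned,
                 split = split))
}

#' Save or load a trained model archive
#'
#' A single JSON archive holding the BiGRU weights, the input shaping
#' specification, the class order, the training hyperparameters, and the
#' preprocessing state and feature mask needed to apply the model to raw
#' feature rows (plus the fingerprint settings when the model was trained
#' from SMILES input).
#'
#' @param model a [BiGRUModel-class].
#' @param path archive file path.
#' @param scaler optional [ScalerState-class].
#' @param mask optional [FeatureMask-class].
#' @param fingerprint optional [fingerprintConfig()].
#' @return `saveModelArchive()` returns `path` invisibly;
#'   `loadModelArchive()` a list with `model`, `scaler`, `mask`,
#'   `fingerprint` (possibly `NULL`).
#' @export
saveModelArchive <- function(model, path, scaler = NULL, mask = NULL,
                             fingerprint = NULL) {
  stopifnot(is(model, "BiGRUModel"))
  cellOut <- function(p) lapply(p, function(x)
    if (is.matrix(x)) apply(x, 1L, identity, simplify = FALSE) else x)
  obj <- list(
    model = list(forward = cellOut(model@forward),
                 backward = cellOut(model@backward),
                 Wout = apply(model@Wout, 1L, identity, simplify = FALSE),
                 bout = model@bout, hidden = model@hidden,
                 chunk = model@chunk, inputDim = model@inputDim,
                 classLevels = model@classLevels, pooling = model@pooling,
                 hyper = model@hyper),
    scaler = if (!is.null(scaler))
      list(median = scaler@median, capLow = scaler@capLow,
           capHigh = scaler@capHigh, center = scaler@center,
           scale = scaler@scale, featureNames = scaler@featureNames,
           provenance = scaler@provenance),
    mask = if (!is.null(mask))
      list(selected = mask@selected, errorRate = mask@errorRate,
           sizeRatio = mask@sizeRatio, fitness = mask@fitness,
           alpha = mask@alpha),
    fingerprint = if (!is.null(fingerprint)) unclass(fingerprint))
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonWrite(obj, path)
  invisible(path)
}

#' @rdname saveModelArchive
#' @export
loadModelArchive <- function(path) {
  obj <- jsonRead(path)
  m <- obj$model
  toMat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  cellIn <- function(p) list(
    Wr = toMat(p$Wr), Wz = toMat(p$Wz), Wh = toMat(p$Wh),
    br = as.numeric(p$br), bz = as.numeric(p$bz), bh = as.numeric(p$bh))
  model <- new("BiGRUModel", forward = cellIn(m$forward),
               backward = cellIn(m$backward),
               Wout = toMat(m$Wout), bout = as.numeric(m$bout),
               hidden = as.integer(m$hidden), chunk = as.integer(m$chunk),
               inputDim = as.integer(m$inputDim),
               classLevels = as.character(m$classLevels),
               pooling = as.character(m$pooling), hyper = as.list(m$hyper),
               report = list())
  scaler <- if (length(obj$scaler))
    new("ScalerState", median = as.numeric(obj$scaler$median),
        capLow = as.numeric(obj$scaler$capLow),
        capHigh = as.numeric(obj$scaler$capHigh),
        center = as.numeric(obj$scaler$center),
        scale = as.numeric(obj$scaler$scale),
        featureNames = as.character(obj$scaler$featureNames),
        provenance = as.character(obj$scaler$provenance))
  mask <- if (length(obj$mask))
    new("FeatureMask", selected = as.logical(obj$mask$selected),
        errorRate = as.numeric(obj$mask$errorRate),
        sizeRatio = as.numeric(obj$mask$sizeRatio),
        fitness = as.numeric(obj$mask$fitness),
        alpha = as.numeric(obj$mask$alpha))
  fingerprint <- if (length(obj$fingerprint))
    fingerprintConfig(obj$fingerprint$nBits, obj$fingerprint$radius,
                      obj$fingerprint$useChirality)
  list(model = model, scaler = scaler, mask = mask,
       fingerprint = fingerprint)
}

#' Predict classes for a CSV of new samples from a model archive
#'
#' Applies the archived preprocessing, feature mask and BiGRU to new data.
#' If the input CSV has a `smiles` column the archived fingerprint settings
#' featurize it first; otherwise it is read as a dense feature CSV (a
#' `label` column, if present, is ignored for prediction). The output CSV
#' has one row per input row: `row`, `predicted`, and one probability
#' column per class. An empty input yields an empty predictions file with
#' a header.
#'
#' @param archivePath path to a [saveModelArchive()] JSON.
#' @param inputCsv path to the input CSV.
#' @param outputCsv optional path; when given, predictions are written
#'   there.
#' @return data.frame of predictions, invisibly when `outputCsv` is given.
#' @export
predictFromArchive <- function(archivePath, inputCsv, outputCsv = NULL) {
  ar <- loadModelArchive(archivePath)
  df <- utils::read.csv(inputCsv, stringsAsFactors = FALSE)
  k <- length(ar$model@classLevels)
  if (nrow(df) == 0L) {
    out <- stats::setNames(
      as.data.frame(matrix(numeric(0), 0L, 2L + k)),
      c("row", "predicted", paste0("p_", ar$model@classLevels)))
  } else {
    if ("smiles" %in% names(df)) {
      if (is.null(ar$fingerprint))
        stop("archive has no fingerprint settings; provide a feature CSV")
      fm <- featurizeTable(df$smiles,
                           if ("label" %in% names(df)) df$label
                           else rep("unknown", nrow(df)),
                           ar$fingerprint)
    } else {
      labels <- if ("label" %in% names(df)) df$label
                else rep("unknown", nrow(df))
      X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
      fm <- FeatureMatrix(X, labels)
    }
    if (!is.null(ar$scaler)) {
      if (ncol(fm) != length(ar$scaler@featureNames))
        stop(sprintf(
          "feature dimension mismatch: archive expects %d features, input has %d",
          length(ar$scaler@featureNames), ncol(fm)))
      fm <- applyPreprocessor(fm, ar$scaler)
    }
    if (!is.null(ar$mask)) fm <- maskFeatureMatrix(fm, ar$mask)
    proba <- predictProba(ar$model, fm)
    pred <- ar$model@classLevels[max.col(proba, ties.method = "first")]
    out <- data.frame(row = seq_len(nrow(proba)), predicted = pred,
                      proba, check.names = FALSE)
    names(out) <- c("row", "predicted", paste0("p_", colnames(proba)))
  }
  if (!is.null(outputCsv)) {
    utils::write.csv(out, outputCsv, row.names = FALSE)
    return(invisible(out))
  }
  out
}
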