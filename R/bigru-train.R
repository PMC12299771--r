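# Adam state and update over a flat list of parameter arrays.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mHat <- state$m[[nm]] / (1 - beta1^state$t)
    vHat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mHat / (sqrt(vHat) + eps)
  }
  list(params = params, state = state)
}

flattenBigruParams <- function(fwd, bwd, Wout, bout) {
  out <- list(Wout = Wout, bout = bout)
  for (nm in names(fwd)) out[[paste0("f.", nm)]] <- fwd[[nm]]
  for (nm in names(bwd)) out[[paste0("b.", nm)]] <- bwd[[nm]]
  out
}

unflattenBigruParams <- function(flat) {
  pick <- function(prefix) {
    nms <- c("Wr", "Wz", "Wh", "br", "bz", "bh")
    stats::setNames(lapply(nms, function(nm) flat[[paste0(prefix, nm)]]), nms)
  }
  list(fwd = pick("f."), bwd = pick("b."),
       Wout = flat$Wout, bout = flat$bout)
}

# Forward + loss + full gradient for one minibatch. yIdx: integer class
# index per row. dropMask: NULL (no dropout) or a 0/scale matrix applied to
# the pooled state (inverted dropout).
bigruBatchGrad <- function(flat, xs, yIdx, pooling, dropMask = NULL) {
  p <- unflattenBigruParams(flat)
  st <- bigruPooledState(p$fwd, p$bwd, xs, pooling)
  pooled <- st$pooled
  if (!is.null(dropMask)) pooled <- pooled * dropMask
  logits <- sweep(tcrossprod(pooled, p$Wout), 2L, p$bout, "+")
  prob <- softmaxRows(logits)
  B <- nrow(prob)
  eps <- 1e-12
  loss <- -mean(log(prob[cbind(seq_len(B), yIdx)] + eps))
  dlogits <- prob
  dlogits[cbind(seq_len(B), yIdx)] <- dlogits[cbind(seq_len(B), yIdx)] - 1
  dlogits <- dlogits / B
  gWout <- crossprod(dlogits, pooled)
  gbout <- colSums(dlogits)
  dPooled <- dlogits %*% p$Wout
  if (!is.null(dropMask)) dPooled <- dPooled * dropMask
  H <- ncol(st$fOut$h)
  if (pooling == "concat") {
    dhF <- dPooled[, seq_len(H), drop = FALSE]
    dhB <- dPooled[, H + seq_len(H), drop = FALSE]
  } else {
    dhF <- dPooled / 2
    dhB <- dPooled / 2
  }
  gF <- gruBackwardPass(p$fwd, st$fOut$cache, dhF)
  gB <- gruBackwardPass(p$bwd, st$bOut$cache, dhB)
  grads <- flattenBigruParams(gF, gB, gWout, gbout)
  list(loss = loss, grads = grads, prob = prob)
}

#' Train a bidirectional GRU classifier
#'
#' Trains a single-layer bidirectional GRU on flat feature vectors. Each
#' length-`D` vector is folded into `T = ceiling(D/chunk)` chunks of width
#' `chunk` (see [reshapeFeatures()]); a forward cell reads the chunks in
#' order and a backward cell in reverse order, their final hidden states
#' are combined (`pooling`), passed through dropout, linearly projected to
#' class logits and trained with cross-entropy using the Adam optimizer.
#' Classes are ordered lexicographically and stored in the model. The run
#' is deterministic under `seed`.
#'
#' @param X numeric matrix (`n x D`) or a [FeatureMatrix-class]
#'   (preprocessed and optionally masked).
#' @param y class labels aligned with rows (ignored when `X` is a
#'   `FeatureMatrix`).
#' @param hidden hidden size H (default 32).
#' @param chunk chunk width F (default `min(D, 128)`).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param batchSize minibatch size (default 32).
#' @param dropout dropout rate on the pooled state, in `[0, 1)` (default 0.2).
#' @param epochs training epochs (default 50).
#' @param pooling `"concat"` (default) or `"mean"` combination of the two
#'   directions' final states.
#' @param seed integer seed for weight init, shuffling and dropout.
#' @return A [BiGRUModel-class]; per-epoch training loss and accuracy are
#'   available via [trainReport()].
#' @examples
#' set.seed(7)
#' X <- rbind(matrix(rnorm(200, 2), 20), matrix(rnorm(200, -2), 20))
#' y <- rep(c("up", "down"), each = 20)
#' m <- trainBiGRU(X, y, hidden = 8, chunk = 5, epochs = 10, seed = 1)
#' mean(predict(m, X) == y)
#' @export
trainBiGRU <- function(X, y = NULL, hidden = 32L, chunk = NULL,
                       learningRate = 1e-3, batchSize = 32L, dropout = 0.2,
                       epochs = 50L, pooling = c("concat", "mean"),
                       seed = 1L) {
  if (is(X, "FeatureMatrix")) {
    y <- sampleLabels(X)
    X <- featureValues(X)
  }
  pooling <- match.arg(pooling)
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  classLevels <- sort(unique(as.character(y)))
  if (length(classLevels) < 2L) stop("need at least 2 classes in y")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  hidden <- as.integer(hidden)
  chunk <- if (is.null(chunk)) min(D, 128L) else as.integer(chunk)
  epochs <- as.integer(epochs); batchSize <- as.integer(batchSize)
  yIdx <- match(as.character(y), classLevels)
  k <- length(classLevels)
  poolDim <- if (pooling == "concat") 2L * hidden else hidden

  withLocalSeed(seed, {
    fwd <- gruCellParams(hidden, chunk)
    bwd <- gruCellParams(hidden, chunk)
    lim <- 1 / sqrt(hidden)
    Wout <- matrix(stats::runif(k * poolDim, -lim, lim), k, poolDim)
    bout <- numeric(k)
    flat <- flattenBigruParams(fwd, bwd, Wout, bout)
    opt <- adamInit(flat)
    lossHist <- accHist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batchSize)
      epLoss <- 0; nCorrect <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + batchSize - 1L, n)]
        xs <- reshapeFeatures(X[idx, , drop = FALSE], chunk)
        dropMask <- if (dropout > 0) {
          keep <- matrix(stats::runif(length(idx) * poolDim) >= dropout,
                         length(idx), poolDim)
          keep / (1 - dropout)
        } else NULL
        bg <- bigruBatchGrad(flat, xs, yIdx[idx], pooling, dropMask)
        upd <- adamStep(flat, bg$grads, opt, learningRate)
        flat <- upd$params; opt <- upd$state
        epLoss <- epLoss + bg$loss * length(idx)
        nCorrect <- nCorrect +
          sum(max.col(bg$prob, ties.method = "first") == yIdx[idx])
      }
      lossHist[ep] <- epLoss / n
      accHist[ep] <- nCorrect / n
    }
    p <- unflattenBigruParams(flat)
    new("BiGRUModel", forward = p$fwd, backward = p$bwd,
        Wout = p$Wout, bout = p$bout,
        hidden = hidden, chunk = chunk, inputDim = as.integer(D),
        classLevels = classLevels, pooling = pooling,
        hyper = list(learningRate = learningRate, batchSize = batchSize,
                     dropout = dropout, epochs = epochs, seed = seed),
        report = list(loss = lossHist, accuracy = accHist, seed = seed))
  })
}

#' Class probabilities from a trained BiGRU
#'
#' Runs the bidirectional forward pass (no dropout) and returns the softmax
#' class probabilities; rows sum to 1. Column order is the model's stored
#' (lexicographic) class order.
#'
#' @param model a [BiGRUModel-class].
#' @param X numeric matrix or [FeatureMatrix-class] with
#'   `ncol == model@inputDim`.
#' @return `n x k` probability matrix with class-name columns.
#' @export
predictProba <- function(model, X) {
  stopifnot(is(model, "BiGRUModel"))
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  if (ncol(X) != model@inputDim)
    stop(sprintf("feature dimension mismatch: model expects %d, data has %d",
                 model@inputDim, ncol(X)))
  xs <- reshapeFeatures(X, model@chunk)
  st <- bigruPooledState(model@forward, model@backward, xs, model@pooling)
  logits <- sweep(tcrossprod(st$pooled, model@Wout), 2L, model@bout, "+")
  prob <- softmaxRows(logits)
  colnames(prob) <- model@classLevels
  prob
}

#' @describeIn BiGRUModel predicted class labels (argmax of
#'   [predictProba()]).
#' @param object a `BiGRUModel`.
#' @param newdata matrix or [FeatureMatrix-class] to classify.
#' @export
setMethod("predict", "BiGRUModel", function(object, newdata, ...) {
  prob <- predictProba(object, newdata)
  object@classLevels[max.col(prob, ties.method = "first")]
})
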