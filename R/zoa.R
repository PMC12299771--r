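#' Zebra Optimization Algorithm control parameters
#'
#' Settings for the herd-based ZOA optimizer: each iteration every zebra is
#' pulled toward the best zebra and the herd average (position update), then
#' receives a random normal "predator-avoidance" perturbation; both moves
#' use greedy acceptance, so only improving zebras endure.
#'
#' @param N herd size (>= 2, default 10).
#' @param c1,c2 influence constants of the best zebra and the herd average
#'   (default 1 each).
#' @param sigmaFrac perturbation intensity as a fraction of the per-dimension
#'   range `ub - lb` (default 0.01).
#' @param maxIter iteration budget (default 20).
#' @return A list of class `zoaControl`.
#' @export
zoaControl <- function(N = 10L, c1 = 1, c2 = 1, sigmaFrac = 0.01,
                       maxIter = 20L) {
  N <- as.integer(N); maxIter <- as.integer(maxIter)
  if (N < 2L) stop("N must be >= 2")
  if (sigmaFrac < 0) stop("sigmaFrac must be >= 0")
  if (maxIter < 0L) stop("maxIter must be >= 0")
  structure(list(N = N, c1 = c1, c2 = c2, sigmaFrac = sigmaFrac,
                 maxIter = maxIter),
            class = "zoaControl")
}

#' ZOA population initialization and step candidates
#'
#' `zoaInit()` draws `X[i, j] = lb[j] + rand * (ub[j] - lb[j])` with one
#' `runif(N * dim)` vector filled column-major.
#'
#' `zoaUpdateStep()` computes the herding candidates
#' `X_new[i,] = X[i,] + c1 * u[i] * (xBest - X[i,]) + c2 * (1 - u[i]) * (xAvg - X[i,])`.
#'
#' `zoaPerturbStep()` adds the predator-avoidance disturbance
#' `X_new = X + sigma * g` with `g` standard normal per coordinate and
#' `sigma` the per-dimension intensity.
#'
#' Clipping to bounds and greedy acceptance happen in [zoaMinimize()].
#'
#' @param N herd size.
#' @param dim dimensionality.
#' @param lower,upper per-dimension bounds (recycled).
#' @param X `N x dim` position matrix.
#' @param xBest best-so-far position.
#' @param xAvg current herd mean.
#' @param c1,c2 influence constants.
#' @param u uniform draws, one per zebra.
#' @param sigma per-dimension perturbation scale (recycled).
#' @param g `N x dim` matrix of standard-normal draws.
#' @return `N x dim` matrix of positions/candidates.
#' @export
zoaInit <- function(N, dim, lower = 0, upper = 1) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  if (any(lower >= upper)) stop("lower must be < upper in every dimension")
  r <- matrix(stats::runif(N * dim), N, dim)
  sweep(sweep(r, 2L, upper - lower, "*"), 2L, lower, "+")
}

#' @rdname zoaInit
#' @export
zoaUpdateStep <- function(X, xBest, xAvg, c1, c2, u) {
  N <- nrow(X)
  Xb <- matrix(xBest, N, ncol(X), byrow = TRUE)
  Xa <- matrix(xAvg, N, ncol(X), byrow = TRUE)
  X + c1 * u * (Xb - X) + c2 * (1 - u) * (Xa - X)
}

#' @rdname zoaInit
#' @export
zoaPerturbStep <- function(X, sigma, g) {
  X + sweep(g, 2L, rep_len(sigma, ncol(X)), "*")
}

#' Minimize an objective with the Zebra Optimization Algorithm
#'
#' Runs the ZOA loop over box bounds: uniform initialization, then per
#' iteration a herding update toward the best zebra and the herd average
#' followed by a normal perturbation with intensity
#' `sigmaFrac * (upper - lower)`; candidates are clipped to the bounds and
#' accepted only on improvement, so the best-so-far trace is non-increasing.
#'
#' @param objective function mapping a length-`dim` position to a finite
#'   scalar to minimize.
#' @param dim dimensionality.
#' @param lower,upper bounds (recycled; default the unit cube, the native
#'   domain of the hyperparameter tuner).
#' @param control a [zoaControl()].
#' @param seed integer seed for all random draws.
#' @return list with `best`, `value`, `trace`, `evaluations`.
#' @examples
#' out <- zoaMinimize(function(x) sum(x^2), dim = 3,
#'                    control = zoaControl(N = 8, maxIter = 30), seed = 1)
#' out$value
#' @export
zoaMinimize <- function(objective, dim, lower = 0, upper = 1,
                        control = zoaControl(), seed = 1L) {
  stopifnot(inherits(control, "zoaControl"))
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  sigma <- control$sigmaFrac * (upper - lower)
  withLocalSeed(seed, {
    N <- control$N
    X <- zoaInit(N, dim, lower, upper)
    fit <- apply(X, 1L, objective)
    if (any(!is.finite(fit))) stop("objective returned a non-finite value")
    i <- which.min(fit)
    best <- X[i, ]; bestFit <- fit[i]
    nEval <- N
    trace <- bestFit
    accept <- function(cand) {
      cand <- t(apply(cand, 1L, clipTo, lower = lower, upper = upper))
      f <- apply(cand, 1L, objective)
      if (any(!is.finite(f))) stop("objective returned a non-finite value")
      better <- f < fit
      X[better, ] <<- cand[better, , drop = FALSE]
      fit[better] <<- f[better]
      j <- which.min(fit)
      if (fit[j] < bestFit) { bestFit <<- fit[j]; best <<- X[j, ] }
      nEval <<- nEval + N
    }
    iter <- 0L
    while (iter < control$maxIter) {
      iter <- iter + 1L
      accept(zoaUpdateStep(X, best, colMeans(X), control$c1, control$c2,
                           stats::runif(N)))
      if (any(sigma > 0))
        accept(zoaPerturbStep(X, sigma, matrix(stats::rnorm(N * dim), N, dim)))
      trace <- c(trace, bestFit)
    }
    list(best = best, value = bestFit, trace = trace, evaluations = nEval)
  })
}

#' The BiGRU hyperparameter search space
#'
#' The closed ranges the tuner searches: learning rate `[1e-4, 1e-2]`
#' (log-uniform decode), GRU units `[32, 256]`, batch size `[16, 128]`,
#' dropout `[0.1, 0.5]`, epochs `[10, 100]` (integers decoded by linear
#' scale then round-half-up).
#'
#' @return A list of class `hyperparameterSpace`; one element per
#'   hyperparameter with fields `type` (`"log"`, `"int"` or `"cont"`) and
#'   `lo`, `hi`.
#' @export
hyperparameterSpace <- function() {
  structure(list(
    learningRate = list(type = "log", lo = 1e-4, hi = 1e-2),
    gruUnits = list(type = "int", lo = 32, hi = 256),
    batchSize = list(type = "int", lo = 16, hi = 128),
    dropout = list(type = "cont", lo = 0.1, hi = 0.5),
    epochs = list(type = "int", lo = 10, hi = 100)),
    class = "hyperparameterSpace")
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Decode a unit-cube position into concrete hyperparameters
#'
#' Maps a position in `[0,1]^dim` onto the closed hyperparameter ranges:
#' log-type parameters decode log-uniformly
#' (`10^(log10(lo) + p*(log10(hi) - log10(lo)))`), integer parameters by a
#' linear scale followed by round-half-up, continuous parameters linearly.
#' Decoded values always lie inside the stated closed ranges.
#'
#' @param position numeric vector in `[0,1]^dim`, one coordinate per
#'   hyperparameter in the order of `space`.
#' @param space a [hyperparameterSpace()].
#' @return Named list of decoded hyperparameter values.
#' @examples
#' decodePosition(rep(0.5, 5), hyperparameterSpace())$learningRate  # 1e-3
#' @export
decodePosition <- function(position, space = hyperparameterSpace()) {
  stopifnot(inherits(space, "hyperparameterSpace"),
            length(position) == length(space))
  position <- clipTo(position, 0, 1)
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (i in seq_along(space)) {
    s <- space[[i]]; p <- position[i]
    out[[i]] <- switch(s$type,
      log = 10^(log10(s$lo) + p * (log10(s$hi) - log10(s$lo))),
      int = as.integer(clipTo(roundHalfUp(s$lo + p * (s$hi - s$lo)),
                              s$lo, s$hi)),
      cont = s$lo + p * (s$hi - s$lo),
      stop("unknown parameter type: ", s$type))
  }
  out
}

#' Classification error rate in percent
#'
#' The tuning fitness: `100 * misclassified / total`.
#'
#' @param yTrue,yPred aligned label vectors.
#' @return Percentage in `[0, 100]`.
#' @examples
#' classifierErrorRate(rep(1, 100), c(rep(1, 95), rep(2, 5)))  # 5
#' @export
classifierErrorRate <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  100 * sum(as.character(yTrue) != as.character(yPred)) / length(yTrue)
}

#' Tune BiGRU hyperparameters with ZOA
#'
#' Minimizes the validation error rate (percent misclassified) of the
#' BiGRU over the unit-cube encoding of [hyperparameterSpace()]: each
#' zebra's position decodes to a configuration, a BiGRU is trained on the
#' training split with it, and the fitness is the percent error on the
#' disjoint validation split. Fitness values are cached by decoded
#' configuration, so duplicate configurations never retrain.
#'
#' @param XTrain,yTrain training split (matrix + labels), disjoint from
#'   validation.
#' @param XVal,yVal validation split.
#' @param control a [zoaControl()].
#' @param space a [hyperparameterSpace()].
#' @param chunk,pooling fixed shaping arguments passed to [trainBiGRU()].
#' @param seed integer seed (optimizer draws and candidate training).
#' @return list with `best` (decoded hyperparameters), `error` (best
#'   validation percent error), `trace` (best-so-far, non-increasing), and
#'   `evaluated` (data.frame of all decoded configurations and fitnesses).
#' @export
tuneBiGRU <- function(XTrain, yTrain, XVal, yVal, control = zoaControl(),
                      space = hyperparameterSpace(), chunk = NULL,
                      pooling = "concat", seed = 1L) {
  if (length(unique(as.character(yVal))) < 2L)
    stop("validation split must contain at least 2 classes")
  cacheEnv <- new.env(parent = emptyenv())
  evaluated <- list()
  trainSeed <- stageSeed(seed, "train")
  objective <- function(pos) {
    cfg <- decodePosition(pos, space)
    key <- paste(vapply(cfg, format, character(1), digits = 15),
                 collapse = "|")
    if (!is.null(cacheEnv[[key]])) return(cacheEnv[[key]])
    model <- trainBiGRU(XTrain, yTrain, hidden = cfg$gruUnits,
                        chunk = chunk, learningRate = cfg$learningRate,
                        batchSize = cfg$batchSize, dropout = cfg$dropout,
                        epochs = cfg$epochs, pooling = pooling,
                        seed = trainSeed)
    err <- classifierErrorRate(yVal, predict(model, XVal))
    cacheEnv[[key]] <- err
    evaluated[[length(evaluated) + 1L]] <<-
      c(unlist(cfg), fitness = err)
    err
  }
  out <- zoaMinimize(objective, dim = length(space), lower = 0, upper = 1,
                     control = control, seed = seed)
  list(best = decodePosition(out$best, space), error = out$value,
       trace = out$trace,
       evaluated = as.data.frame(do.call(rbind, evaluated)))
}
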