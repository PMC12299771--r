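#' Bald Eagle Search control parameters
#'
#' Settings for the three-phase Bald Eagle Search (BES) swarm optimizer.
#' Each iteration every eagle passes a select phase (move toward the
#' best/mean), a search phase (spiral exploration with sin/cos weights) and
#' a swoop phase (exploitation with sinh/cosh weights toward the best),
#' with greedy per-phase acceptance.
#'
#' @param N population size (>= 2, default 30).
#' @param alphaSelect select-phase gain, in `[1.5, 2]` (default 2).
#' @param aParam spiral angle parameter, in `[5, 10]` (default 10).
#' @param RParam spiral radius parameter, in `[0.5, 2]` (default 1.5).
#' @param c1,c2 swoop intensity constants, in `(1, 2)` (default 1.5).
#' @param maxIter iteration budget (>= 0, default 100).
#' @return A list of class `besControl`.
#' @export
besControl <- function(N = 30L, alphaSelect = 2, aParam = 10, RParam = 1.5,
                       c1 = 1.5, c2 = 1.5, maxIter = 100L) {
  N <- as.integer(N); maxIter <- as.integer(maxIter)
  if (N < 2L) stop("N must be >= 2")
  if (alphaSelect < 1.5 || alphaSelect > 2) stop("alphaSelect must be in [1.5, 2]")
  if (aParam < 5 || aParam > 10) stop("aParam must be in [5, 10]")
  if (RParam < 0.5 || RParam > 2) stop("RParam must be in [0.5, 2]")
  if (c1 <= 1 || c1 >= 2 || c2 <= 1 || c2 >= 2) stop("c1, c2 must be in (1, 2)")
  if (maxIter < 0L) stop("maxIter must be >= 0")
  structure(list(N = N, alphaSelect = alphaSelect, aParam = aParam,
                 RParam = RParam, c1 = c1, c2 = c2, maxIter = maxIter),
            class = "besControl")
}

.EPS_NORM <- 1e-12   # guard for max-normalization denominators
.THETA_CAP <- 20     # swoop angle cap before sinh/cosh

#' Initialize a BES population
#'
#' Draws every coordinate uniformly inside its bounds:
#' `P[i, j] = lb[j] + rand * (ub[j] - lb[j])`. The `N x dim` random draws
#' are taken as one `runif(N * dim)` vector filled column-major.
#'
#' @param N population size.
#' @param dim dimensionality.
#' @param lower,upper per-dimension bounds (scalars recycled); must satisfy
#'   `lower < upper` elementwise.
#' @return `N x dim` matrix of positions.
#' @examples
#' set.seed(1); P <- besInit(5, 2, -5, 5); range(P)
#' @export
besInit <- function(N, dim, lower, upper) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  if (any(lower >= upper)) stop("lower must be < upper in every dimension")
  r <- matrix(stats::runif(N * dim), N, dim)
  sweep(sweep(r, 2L, upper - lower, "*"), 2L, lower, "+")
}

#' BES phase candidate positions
#'
#' Pure candidate computations for the three BES phases, given the random
#' draws explicitly (so they can be verified against a line-by-line
#' transcription of the update rules). Bound clipping and greedy acceptance
#' are applied by [besMinimize()], not here.
#'
#' `besSelectStep()`: `P_new[i,] = pBest + alphaSelect * r6[i] * (pMean - P[i,])`.
#'
#' `besSearchStep()`: spiral weights `theta = a*pi*r7`,
#' `r = theta + R*r8`, `xr = r*sin(theta)`, `yr = r*cos(theta)`, each
#' max-|.|-normalized over the population, drive
#' `P_new[i,] = P[i,] + y[i]*(P[i,] - P[i+1,]) + x[i]*(P[i,] - pMean)` with
#' index `i+1` wrapping cyclically.
#'
#' `besSwoopStep()`: polar weights with `theta = a*pi*r10` (capped at 20
#' before the hyperbolic functions), `r = theta`, `xr = r*sinh(theta)`,
#' `yr = r*cosh(theta)`, max-normalized, drive
#' `P_new[i,] = r9[i]*pBest + x1[i]*(P[i,] - c1*pMean) + y1[i]*(P[i,] - c2*pBest)`.
#'
#' @param P `N x dim` matrix of current positions.
#' @param pBest best-so-far position (length dim).
#' @param pMean current population mean (length dim).
#' @param alphaSelect select-phase gain.
#' @param a,R spiral parameters.
#' @param c1,c2 swoop intensities.
#' @param r6,r7,r8,r9,r10 uniform draws, one per eagle.
#' @return `N x dim` matrix of candidate positions.
#' @export
besSelectStep <- function(P, pBest, pMean, alphaSelect, r6) {
  N <- nrow(P)
  Pb <- matrix(pBest, N, ncol(P), byrow = TRUE)
  Pm <- matrix(pMean, N, ncol(P), byrow = TRUE)
  Pb + alphaSelect * r6 * (Pm - P)
}

#' @rdname besSelectStep
#' @export
besSearchStep <- function(P, pMean, a, R, r7, r8) {
  N <- nrow(P)
  theta <- a * pi * r7
  r <- theta + R * r8
  xr <- r * sin(theta)
  yr <- r * cos(theta)
  x <- xr / (max(abs(xr)) + .EPS_NORM)
  y <- yr / (max(abs(yr)) + .EPS_NORM)
  Pnext <- P[c(seq_len(N)[-1L], 1L), , drop = FALSE]
  Pm <- matrix(pMean, N, ncol(P), byrow = TRUE)
  P + y * (P - Pnext) + x * (P - Pm)
}

#' @rdname besSelectStep
#' @export
besSwoopStep <- function(P, pBest, pMean, a, c1, c2, r9, r10) {
  N <- nrow(P)
  theta <- pmin(a * pi * r10, .THETA_CAP)
  r <- theta
  xr <- r * sinh(theta)
  yr <- r * cosh(theta)
  x1 <- xr / (max(abs(xr)) + .EPS_NORM)
  y1 <- yr / (max(abs(yr)) + .EPS_NORM)
  Pb <- matrix(pBest, N, ncol(P), byrow = TRUE)
  Pm <- matrix(pMean, N, ncol(P), byrow = TRUE)
  r9 * Pb + x1 * (P - c1 * Pm) + y1 * (P - c2 * Pb)
}

# Evaluate candidates, clip to bounds, accept greedily; returns updated
# state list(P, fit, best, bestFit).
besGreedyAccept <- function(state, cand, objective, lower, upper) {
  cand <- t(apply(cand, 1L, clipTo, lower = lower, upper = upper))
  f <- apply(cand, 1L, objective)
  if (any(!is.finite(f))) stop("objective returned a non-finite value")
  better <- f < state$fit
  state$P[better, ] <- cand[better, , drop = FALSE]
  state$fit[better] <- f[better]
  i <- which.min(state$fit)
  if (state$fit[i] < state$bestFit) {
    state$bestFit <- state$fit[i]
    state$best <- state$P[i, ]
  }
  state
}

#' Minimize an objective with Bald Eagle Search
#'
#' Runs the full three-phase BES loop: after uniform initialization inside
#' the bounds, each iteration applies the select, search and swoop phases to
#' the whole population, clipping out-of-bounds candidates to the violated
#' bound and accepting a candidate only if it improves that eagle's fitness
#' (greedy). The best-so-far trace is therefore non-increasing.
#'
#' @param objective function mapping a length-`dim` numeric position to a
#'   finite scalar to be minimized.
#' @param dim dimensionality.
#' @param lower,upper bounds (scalars recycled to `dim`).
#' @param control a [besControl()].
#' @param seed integer seed controlling all random draws of the run.
#' @return list with `best` (position), `value` (best fitness), `trace`
#'   (best-so-far fitness after initialization and after each iteration),
#'   and `evaluations` (number of objective calls).
#' @examples
#' out <- besMinimize(function(x) sum(x^2), dim = 2, lower = -5, upper = 5,
#'                    control = besControl(N = 10, maxIter = 25), seed = 1)
#' out$value
#' @export
besMinimize <- function(objective, dim, lower, upper,
                        control = besControl(), seed = 1L) {
  stopifnot(inherits(control, "besControl"))
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  withLocalSeed(seed, {
    N <- control$N
    P <- besInit(N, dim, lower, upper)
    fit <- apply(P, 1L, objective)
    if (any(!is.finite(fit))) stop("objective returned a non-finite value")
    i <- which.min(fit)
    state <- list(P = P, fit = fit, best = P[i, ], bestFit = fit[i])
    nEval <- N
    trace <- state$bestFit
    iter <- 0L
    while (iter < control$maxIter) {
      iter <- iter + 1L
      # select
      pMean <- colMeans(state$P)
      cand <- besSelectStep(state$P, state$best, pMean, control$alphaSelect,
                            stats::runif(N))
      state <- besGreedyAccept(state, cand, objective, lower, upper)
      # search
      pMean <- colMeans(state$P)
      cand <- besSearchStep(state$P, pMean, control$aParam, control$RParam,
                            stats::runif(N), stats::runif(N))
      state <- besGreedyAccept(state, cand, objective, lower, upper)
      # swoop
      pMean <- colMeans(state$P)
      cand <- besSwoopStep(state$P, state$best, pMean, control$aParam,
                           control$c1, control$c2,
                           stats::runif(N), stats::runif(N))
      state <- besGreedyAccept(state, cand, objective, lower, upper)
      nEval <- nEval + 3L * N
      trace <- c(trace, state$bestFit)
    }
    list(best = state$best, value = state$bestFit, trace = trace,
         evaluations = nEval)
  })
}
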