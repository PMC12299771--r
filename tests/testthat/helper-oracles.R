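# Independent literal transcriptions of the update rules, written as plain
# scalar loops. These deliberately avoid the package's vectorized code
# paths so they can serve as oracles for it.

EPS_ORACLE <- 1e-12
THETA_CAP_ORACLE <- 20

oracleInit <- function(N, dim, lower, upper, randMat) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  P <- matrix(0, N, dim)
  for (i in seq_len(N))
    for (j in seq_len(dim))
      P[i, j] <- lower[j] + randMat[i, j] * (upper[j] - lower[j])
  P
}

oracleSelect <- function(P, pBest, pMean, alphaSelect, r6) {
  out <- P * 0
  for (i in seq_len(nrow(P)))
    for (j in seq_len(ncol(P)))
      out[i, j] <- pBest[j] + alphaSelect * r6[i] * (pMean[j] - P[i, j])
  out
}

oracleSearch <- function(P, pMean, a, R, r7, r8) {
  N <- nrow(P)
  theta <- xr <- yr <- numeric(N)
  for (i in seq_len(N)) {
    theta[i] <- a * pi * r7[i]
    r <- theta[i] + R * r8[i]
    xr[i] <- r * sin(theta[i])
    yr[i] <- r * cos(theta[i])
  }
  mx <- max(abs(xr)); my <- max(abs(yr))
  out <- P * 0
  for (i in seq_len(N)) {
    x <- xr[i] / (mx + EPS_ORACLE)
    y <- yr[i] / (my + EPS_ORACLE)
    inext <- if (i == N) 1L else i + 1L
    for (j in seq_len(ncol(P)))
      out[i, j] <- P[i, j] + y * (P[i, j] - P[inext, j]) +
        x * (P[i, j] - pMean[j])
  }
  out
}

oracleSwoop <- function(P, pBest, pMean, a, c1, c2, r9, r10) {
  N <- nrow(P)
  xr <- yr <- numeric(N)
  for (i in seq_len(N)) {
    theta <- min(a * pi * r10[i], THETA_CAP_ORACLE)
    r <- theta
    xr[i] <- r * sinh(theta)
    yr[i] <- r * cosh(theta)
  }
  mx <- max(abs(xr)); my <- max(abs(yr))
  out <- P * 0
  for (i in seq_len(N)) {
    x1 <- xr[i] / (mx + EPS_ORACLE)
    y1 <- yr[i] / (my + EPS_ORACLE)
    for (j in seq_len(ncol(P)))
      out[i, j] <- r9[i] * pBest[j] + x1 * (P[i, j] - c1 * pMean[j]) +
        y1 * (P[i, j] - c2 * pBest[j])
  }
  out
}

oracleGruStep <- function(params, hPrev, x) {
  H <- length(hPrev)
  sig <- function(v) 1 / (1 + exp(-v))
  cc <- c(hPrev, x)
  r <- z <- hT <- h <- numeric(H)
  for (u in seq_len(H)) {
    r[u] <- sig(sum(params$Wr[u, ] * cc) + params$br[u])
    z[u] <- sig(sum(params$Wz[u, ] * cc) + params$bz[u])
  }
  ccH <- c(r * hPrev, x)
  for (u in seq_len(H))
    hT[u] <- tanh(sum(params$Wh[u, ] * ccH) + params$bh[u])
  for (u in seq_len(H))
    h[u] <- (1 - z[u]) * hPrev[u] + z[u] * hT[u]
  h
}

oracleZoaUpdate <- function(X, xBest, xAvg, c1, c2, u) {
  out <- X * 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X)))
      out[i, j] <- X[i, j] + c1 * u[i] * (xBest[j] - X[i, j]) +
        c2 * (1 - u[i]) * (xAvg[j] - X[i, j])
  out
}

oracleZoaPerturb <- function(X, sigma, g) {
  sigma <- rep_len(sigma, ncol(X))
  out <- X * 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X)))
      out[i, j] <- X[i, j] + sigma[j] * g[i, j]
  out
}

# Brute-force metrics: explicit double loops over the contingency table and
# over positive/negative score pairs for the AUC (ties count 1/2).
bruteMetrics <- function(yTrue, yPred, proba) {
  classes <- sort(unique(yTrue))
  n <- length(yTrue)
  out <- list()
  for (cl in classes) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(n)) {
      p <- yPred[i] == cl; t <- yTrue[i] == cl
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    pos <- which(yTrue == cl); neg <- which(yTrue != cl)
    wins <- 0
    for (i in pos) for (j in neg) {
      if (proba[i, cl] > proba[j, cl]) wins <- wins + 1
      else if (proba[i, cl] == proba[j, cl]) wins <- wins + 0.5
    }
    out[[cl]] <- c(accuracy = (tp + tn) / n, precision = prec, recall = rec,
                   f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
                   auc = wins / (length(pos) * length(neg)))
  }
  do.call(rbind, out)
}

# Nearest-centroid classifier, the signal-strength sanity oracle for the
# synthetic generator.
nearestCentroidAccuracy <- function(X, y) {
  y <- as.factor(y)
  cents <- t(sapply(levels(y), function(cl) colMeans(X[y == cl, , drop = FALSE])))
  pred <- levels(y)[apply(X, 1L, function(row)
    which.min(colSums((t(cents) - row)^2)))]
  mean(pred == as.character(y))
}
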