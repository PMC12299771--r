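sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create GRU cell parameters
#'
#' Allocates the gate weight matrices and biases of one GRU cell. Each of
#' `Wr`, `Wz`, `Wh` is `H x (H + F)` and acts on the concatenation of the
#' previous hidden state and the current input chunk; biases have length
#' `H`. Weights are drawn uniformly in `[-1/sqrt(H), 1/sqrt(H)]` from the
#' current RNG stream; biases start at zero.
#'
#' @param H hidden size.
#' @param Fw input chunk width.
#' @return Named list `Wr`, `Wz`, `Wh`, `br`, `bz`, `bh`.
#' @export
gruCellParams <- function(H, Fw) {
  lim <- 1 / sqrt(H)
  rnd <- function() matrix(stats::runif(H * (H + Fw), -lim, lim), H, H + Fw)
  list(Wr = rnd(), Wz = rnd(), Wh = rnd(),
       br = numeric(H), bz = numeric(H), bh = numeric(H))
}

#' One GRU cell step
#'
#' Computes one recurrence step of the gated recurrent unit:
#' \deqn{r_t = \sigma(W_r [h_{t-1}, x_t] + b_r)}
#' \deqn{z_t = \sigma(W_z [h_{t-1}, x_t] + b_z)}
#' \deqn{\tilde h_t = \tanh(W_h [r_t \odot h_{t-1}, x_t] + b_h)}
#' \deqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t}
#' The reset gate `r_t` controls how much of the past state enters the
#' candidate state; the update gate `z_t` blends the past state with the
#' candidate.
#'
#' @param params a [gruCellParams()] list.
#' @param hPrev previous hidden state: length-`H` vector or `B x H` matrix.
#' @param x current input chunk: length-`F` vector or `B x F` matrix.
#' @return Hidden state of the same shape as `hPrev`.
#' @examples
#' p <- list(Wr = matrix(0, 2, 3), Wz = matrix(0, 2, 3),
#'           Wh = matrix(0, 2, 3), br = c(0, 0), bz = c(0, 0), bh = c(0, 0))
#' gruCellStep(p, c(1, -1), 0.5)  # zero weights: h = 0.5 * hPrev
#' @export
gruCellStep <- function(params, hPrev, x) {
  vec <- is.null(dim(hPrev))
  if (vec) {
    hPrev <- matrix(hPrev, 1L)
    x <- matrix(x, 1L)
  }
  H <- ncol(hPrev)
  if (ncol(hPrev) + ncol(x) != ncol(params$Wr))
    stop(sprintf("shape mismatch: cell expects H+F = %d, got %d",
                 ncol(params$Wr), ncol(hPrev) + ncol(x)))
  cc <- cbind(hPrev, x)
  r <- sigmoid(sweep(tcrossprod(cc, params$Wr), 2L, params$br, "+"))
  z <- sigmoid(sweep(tcrossprod(cc, params$Wz), 2L, params$bz, "+"))
  ccH <- cbind(r * hPrev, x)
  hT <- tanh(sweep(tcrossprod(ccH, params$Wh), 2L, params$bh, "+"))
  h <- (1 - z) * hPrev + z * hT
  if (vec) drop(h) else h
}

#' Reshape flat feature vectors into a chunk sequence
#'
#' Folds a length-`D` feature vector (or each row of an `n x D` matrix)
#' row-major into `T = ceiling(D / chunk)` consecutive chunks of width
#' `chunk`; the final chunk is zero-padded. This shaping turns a flat
#' fingerprint into the timestep sequence the recurrent classifier
#' consumes, and is stored with a trained model so prediction uses the
#' identical shaping.
#'
#' @param x numeric vector (length `D`) or matrix (`n x D`).
#' @param chunk chunk width `F >= 1`.
#' @return For a vector, a `T x F` matrix (one chunk per row); for a
#'   matrix, a list of `T` matrices of size `n x F` (chunk `t` holds
#'   columns `(t-1)*F + 1 ... t*F`).
#' @examples
#' reshapeFeatures(1:5, 2)       # rows: 1 2 / 3 4 / 5 0
#' length(reshapeFeatures(matrix(0, 3, 2048), 128))  # 16 chunks
#' @export
reshapeFeatures <- function(x, chunk) {
  chunk <- as.integer(chunk)
  if (chunk < 1L) stop("chunk must be >= 1")
  if (is.null(dim(x))) {
    D <- length(x)
    Tn <- ceiling(D / chunk)
    padded <- c(as.numeric(x), numeric(Tn * chunk - D))
    matrix(padded, Tn, chunk, byrow = TRUE)
  } else {
    D <- ncol(x)
    Tn <- ceiling(D / chunk)
    lapply(seq_len(Tn), function(t) {
      lo <- (t - 1L) * chunk + 1L
      hi <- min(t * chunk, D)
      block <- x[, lo:hi, drop = FALSE]
      if (hi - lo + 1L < chunk)
        block <- cbind(block, matrix(0, nrow(x), chunk - (hi - lo + 1L)))
      unname(block)
    })
  }
}

# Forward pass of one direction over a chunk list; keeps the caches BPTT
# needs. xs: list of T matrices (B x F).
gruForwardPass <- function(params, xs) {
  B <- nrow(xs[[1L]])
  H <- nrow(params$Wr)
  h <- matrix(0, B, H)
  Tn <- length(xs)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- xs[[t]]
    cc <- cbind(h, x)
    r <- sigmoid(sweep(tcrossprod(cc, params$Wr), 2L, params$br, "+"))
    z <- sigmoid(sweep(tcrossprod(cc, params$Wz), 2L, params$bz, "+"))
    ccH <- cbind(r * h, x)
    hT <- tanh(sweep(tcrossprod(ccH, params$Wh), 2L, params$bh, "+"))
    hNew <- (1 - z) * h + z * hT
    cache[[t]] <- list(hPrev = h, x = x, cc = cc, r = r, z = z, hT = hT)
    h <- hNew
  }
  list(h = h, cache = cache)
}

# Backpropagation through time for one direction. dhFinal: gradient at the
# final hidden state (B x H). Returns parameter gradients.
gruBackwardPass <- function(params, cache, dhFinal) {
  H <- nrow(params$Wr)
  g <- list(Wr = params$Wr * 0, Wz = params$Wz * 0, Wh = params$Wh * 0,
            br = numeric(H), bz = numeric(H), bh = numeric(H))
  dh <- dhFinal
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    dz <- dh * (cc$hT - cc$hPrev)
    dhT <- dh * cc$z
    dhPrev <- dh * (1 - cc$z)
    dpreH <- dhT * (1 - cc$hT^2)
    ccH <- cbind(cc$r * cc$hPrev, cc$x)
    g$Wh <- g$Wh + crossprod(dpreH, ccH)
    g$bh <- g$bh + colSums(dpreH)
    dccH <- dpreH %*% params$Wh
    dr <- dccH[, seq_len(H), drop = FALSE] * cc$hPrev
    dhPrev <- dhPrev + dccH[, seq_len(H), drop = FALSE] * cc$r
    dpreR <- dr * cc$r * (1 - cc$r)
    dpreZ <- dz * cc$z * (1 - cc$z)
    g$Wr <- g$Wr + crossprod(dpreR, cc$cc)
    g$br <- g$br + colSums(dpreR)
    g$Wz <- g$Wz + crossprod(dpreZ, cc$cc)
    g$bz <- g$bz + colSums(dpreZ)
    dcc <- dpreR %*% params$Wr + dpreZ %*% params$Wz
    dh <- dhPrev + dcc[, seq_len(H), drop = FALSE]
  }
  g
}

softmaxRows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Pooled bidirectional state for a batch: forward cell reads chunks
# 1..T, backward cell reads T..1; final states are combined.
bigruPooledState <- function(fwd, bwd, xs, pooling) {
  fOut <- gruForwardPass(fwd, xs)
  bOut <- gruForwardPass(bwd, rev(xs))
  pooled <- switch(pooling,
    concat = cbind(fOut$h, bOut$h),
    mean = (fOut$h + bOut$h) / 2)
  list(pooled = pooled, fOut = fOut, bOut = bOut)
}
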