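test_that("the GRU cell obeys its closed-form limits", {
  p <- list(Wr = matrix(0, 2, 3), Wz = matrix(0, 2, 3), Wh = matrix(0, 2, 3),
            br = c(0, 0), bz = c(0, 0), bh = c(0, 0))
  h <- c(0.8, -0.4)
  # zero weights: r = z = 0.5, candidate 0, so h_t = 0.5 * h_prev
  expect_equal(gruCellStep(p, h, 1), 0.5 * h, tolerance = 1e-12)
  # update gate forced to 0 (large negative bias): pure carry of h_prev
  p2 <- p; p2$bz <- c(-50, -50)
  expect_equal(gruCellStep(p2, h, 1), h, tolerance = 1e-8)
  # shape mismatch surfaces
  expect_error(gruCellStep(p, c(1, 2, 3), 1), "shape")
})

test_that("one fixed cell step matches the frozen transcription value", {
  W <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 2, 3, byrow = TRUE)
  p <- list(Wr = W, Wz = W, Wh = W, br = c(0, 0), bz = c(0, 0), bh = c(0, 0))
  got <- gruCellStep(p, c(0, 0), 1)
  expect_equal(got, c(0.1673423502756713, 0.3467494396881143),
               tolerance = 1e-10)
  expect_equal(got, oracleGruStep(p, c(0, 0), 1), tolerance = 1e-12)
})

test_that("the cell matches the scalar oracle on randomized shapes", {
  for (i in 1:20) {
    set.seed(100 + i)
    H <- sample(1:5, 1); Fw <- sample(1:4, 1)
    p <- randomGruParams(H, Fw, seed = 100 + i)
    h <- rnorm(H); x <- rnorm(Fw)
    expect_equal(gruCellStep(p, h, x), oracleGruStep(p, h, x),
                 tolerance = 1e-8)
  }
})

test_that("feature reshaping chunks row-major with zero padding", {
  m <- reshapeFeatures(1:5, 2)
  expect_equal(m, matrix(c(1, 2, 3, 4, 5, 0), 3, 2, byrow = TRUE))
  expect_identical(nrow(reshapeFeatures(numeric(2048), 128)), 16L)
  expect_identical(nrow(reshapeFeatures(numeric(7), 7)), 1L)
  # matrix form agrees with the vector form rowwise
  X <- matrix(rnorm(3 * 5), 3, 5)
  chunks <- reshapeFeatures(X, 2)
  expect_length(chunks, 3L)
  expect_equal(chunks[[3]][2, ], reshapeFeatures(X[2, ], 2)[3, ])
})

test_that("analytic gradients match finite differences", {
  set.seed(8)
  n <- 6; D <- 6; H <- 3; Fw <- 2
  X <- matrix(rnorm(n * D), n, D)
  yIdx <- rep(1:2, 3)
  fwd <- randomGruParams(H, Fw, 1); bwd <- randomGruParams(H, Fw, 2)
  Wout <- matrix(rnorm(2 * 2 * H), 2, 2 * H); bout <- rnorm(2)
  flat <- polygru:::flattenBigruParams(fwd, bwd, Wout, bout)
  xs <- reshapeFeatures(X, Fw)
  bg <- polygru:::bigruBatchGrad(flat, xs, yIdx, "concat")
  lossAt <- function(fl) polygru:::bigruBatchGrad(fl, xs, yIdx, "concat")$loss
  eps <- 1e-6
  for (nm in c("Wout", "f.Wh", "b.Wr", "f.bz", "b.bh")) {
    idx <- sample(length(flat[[nm]]), 3)
    for (i in idx) {
      up <- flat; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- flat; dn[[nm]][i] <- dn[[nm]][i] - eps
      numeric <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_equal(bg$grads[[nm]][i], numeric, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic and loss decreases early", {
  d <- makePreprocessed(nPerClass = 30, D = 16, nInformative = 6, seed = 6)
  m1 <- trainBiGRU(d$fm, hidden = 8, chunk = 4, epochs = 8, seed = 3)
  m2 <- trainBiGRU(d$fm, hidden = 8, chunk = 4, epochs = 8, seed = 3)
  expect_equal(tail(trainReport(m1)$loss, 1), tail(trainReport(m2)$loss, 1),
               tolerance = 1e-6)
  expect_identical(m1@Wout, m2@Wout)
  # learning rate 1e-3: loss over the first 5 epochs trends down
  loss <- trainReport(m1)$loss
  expect_lt(loss[5], loss[1])
  expect_identical(length(loss), 8L)
})

test_that("the classifier fits separable data and stalls on constant input", {
  d <- makePreprocessed(nPerClass = 40, D = 32, nInformative = 8, seed = 9)
  m <- trainBiGRU(d$fm, hidden = 16, chunk = 8, epochs = 40, dropout = 0,
                  learningRate = 3e-3, seed = 1)
  expect_gte(max(trainReport(m)$accuracy), 0.95)
  # constant features carry no signal: accuracy stays near the
  # majority-class rate (1/2 for a balanced 2-class problem)
  Xc <- matrix(1, 60, 8)
  yc <- rep(c("a", "b"), 30)
  mc <- trainBiGRU(Xc, yc, hidden = 4, chunk = 4, epochs = 10, dropout = 0,
                   seed = 2)
  expect_lt(abs(tail(trainReport(mc)$accuracy, 1) - 0.5), 0.2)
  # degenerate inputs error
  expect_error(trainBiGRU(Xc[1, , drop = FALSE], "a"), "at least 2")
  expect_error(trainBiGRU(Xc, rep("a", 60)), "classes")
})

test_that("probabilities are normalized, deterministic and shape-checked", {
  d <- makePreprocessed(nPerClass = 20, D = 12, nInformative = 4, seed = 2)
  m <- trainBiGRU(d$fm, hidden = 6, chunk = 4, epochs = 5, seed = 1)
  X <- featureValues(d$fm)
  p <- predictProba(m, X)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_identical(colnames(p), sort(levels(sampleLabels(d$fm))))
  # duplicate rows give identical probability rows
  p2 <- predictProba(m, X[c(1, 1), ])
  expect_identical(p2[1, ], p2[2, ])
  # zero output projection: exactly uniform probabilities
  m0 <- m
  m0@Wout[] <- 0; m0@bout[] <- 0
  expect_true(all(abs(predictProba(m0, X) - 1 / 3) < 1e-12))
  expect_error(predictProba(m, X[, 1:5]), "mismatch")
})

test_that("with tied weights, reversing the sequence swaps the two directions", {
  p <- randomGruParams(4, 3, seed = 31)
  X <- matrix(rnorm(5 * 9), 5, 9)
  xs <- reshapeFeatures(X, 3)
  st <- polygru:::bigruPooledState(p, p, xs, "concat")
  rv <- polygru:::bigruPooledState(p, p, rev(xs), "concat")
  expect_equal(rv$pooled[, 1:4], st$pooled[, 5:8], tolerance = 1e-12)
  expect_equal(rv$pooled[, 5:8], st$pooled[, 1:4], tolerance = 1e-12)
})
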