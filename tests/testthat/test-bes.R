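test_that("population initialization is uniform-in-bounds and seeded", {
  set.seed(7)
  P <- besInit(30, 10, -5, 5)
  expect_true(all(P >= -5 & P <= 5))
  expect_identical(dim(P), c(30L, 10L))
  set.seed(7)
  expect_identical(besInit(30, 10, -5, 5), P)
  # direct substitution: lb + rand * (ub - lb)
  set.seed(3)
  r <- matrix(runif(6), 3, 2)
  set.seed(3)
  expect_equal(besInit(3, 2, 0, 10), 10 * r)
  expect_error(besInit(3, 2, 1, 1), "lower")
})

test_that("phase candidates match the scalar-transcription oracle", {
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(2:6, 1); d <- sample(1:4, 1)
    P <- matrix(rnorm(N * d), N, d)
    pBest <- rnorm(d); pMean <- colMeans(P)
    r6 <- runif(N); r7 <- runif(N); r8 <- runif(N)
    r9 <- runif(N); r10 <- runif(N)
    a <- runif(1, 5, 10); R <- runif(1, 0.5, 2)
    c1 <- runif(1, 1.01, 1.99); c2 <- runif(1, 1.01, 1.99)
    al <- runif(1, 1.5, 2)
    expect_equal(besSelectStep(P, pBest, pMean, al, r6),
                 oracleSelect(P, pBest, pMean, al, r6), tolerance = 1e-8)
    expect_equal(besSearchStep(P, pMean, a, R, r7, r8),
                 oracleSearch(P, pMean, a, R, r7, r8), tolerance = 1e-8)
    expect_equal(besSwoopStep(P, pBest, pMean, a, c1, c2, r9, r10),
                 oracleSwoop(P, pBest, pMean, a, c1, c2, r9, r10),
                 tolerance = 1e-8)
  }
})

test_that("phase candidates honour their degenerate closed forms", {
  # select: P_i = [0], best = [2], mean = [1], alpha = 2, r6 = 0.5 -> [3]
  expect_equal(drop(besSelectStep(matrix(0), 2, 1, 2, 0.5)), 3)
  # select collapses onto the best when mean equals every position
  P <- matrix(1:6 * 0 + 2, 3, 2)
  expect_equal(besSelectStep(P, c(9, -9), c(2, 2), 2, runif(3)),
               matrix(c(9, -9), 3, 2, byrow = TRUE))
  # search: zero angles give zero weights, hence no move
  P <- matrix(rnorm(6), 3, 2)
  expect_equal(besSearchStep(P, colMeans(P), 5, 1.5, rep(0, 3), rep(0, 3)), P)
  # search: weights are max-normalized to 1 (up to the epsilon guard)
  r7 <- runif(3, 0.2, 0.8); r8 <- runif(3, 0.2, 0.8)
  theta <- 5 * pi * r7; r <- theta + 1.5 * r8
  expect_equal(max(abs((r * sin(theta)) / (max(abs(r * sin(theta))) + 1e-12))),
               1, tolerance = 1e-9)
  # swoop with zero angle and r9 = 1 collapses onto the best
  expect_equal(besSwoopStep(matrix(rnorm(4), 2), c(3, -1), c(0, 0), 5,
                            1.5, 1.5, c(1, 1), c(0, 0)),
               matrix(c(3, -1), 2, 2, byrow = TRUE))
  # both difference terms vanish when P = c1*mean = c2*best: candidate
  # reduces to r9 * best exactly
  P1 <- matrix(c(3, 3), 2, 1)
  cand <- besSwoopStep(P1, pBest = 3 / 1.5, pMean = 3 / 1.2, a = 5,
                       c1 = 1.2, c2 = 1.5, r9 = c(0.25, 0.5),
                       r10 = c(0.3, 0.6))
  expect_equal(drop(cand), c(0.25, 0.5) * (3 / 1.5), tolerance = 1e-12)
})

test_that("besMinimize keeps bounds, monotone trace and iteration contract", {
  seen <- new.env(); seen$bad <- FALSE
  obj <- function(x) {
    if (any(x < -3 - 1e-12 | x > 4 + 1e-12)) seen$bad <- TRUE
    sum((x - 1)^2)
  }
  out <- besMinimize(obj, dim = 3, lower = -3, upper = 4,
                     control = besControl(N = 8, maxIter = 30), seed = 5)
  expect_false(seen$bad)
  expect_true(all(diff(out$trace) <= 0))
  expect_length(out$trace, 31L)
  expect_true(all(out$best >= -3 & out$best <= 4))
  # maxIter = 0 returns the best of the initial population
  out0 <- besMinimize(function(x) sum(x^2), 2, -1, 1,
                      besControl(N = 6, maxIter = 0), seed = 2)
  expect_length(out0$trace, 1L)
  expect_identical(out0$evaluations, 6L)
  # constant landscape: flat trace at the constant
  outc <- besMinimize(function(x) 7, 2, -1, 1,
                      besControl(N = 5, maxIter = 10), seed = 1)
  expect_true(all(outc$trace == 7))
  expect_error(
    besMinimize(function(x) NaN, 2, -1, 1, besControl(N = 4, maxIter = 1)),
    "non-finite")
})

test_that("besMinimize is deterministic under seed and beats random search", {
  o1 <- besMinimize(function(x) sum(x^2), 4, -5, 5,
                    control = besControl(N = 10, maxIter = 20), seed = 9)
  o2 <- besMinimize(function(x) sum(x^2), 4, -5, 5,
                    control = besControl(N = 10, maxIter = 20), seed = 9)
  expect_identical(o1$best, o2$best)
  expect_identical(o1$trace, o2$trace)
  # same evaluation budget, 2-D sphere, median over 10 seeds
  besVals <- randVals <- numeric(10)
  for (s in 1:10) {
    out <- besMinimize(function(x) sum(x^2), 2, -10, 10,
                       control = besControl(N = 10, maxIter = 30), seed = s)
    besVals[s] <- out$value
    set.seed(s + 1000)
    Xr <- matrix(runif(out$evaluations * 2, -10, 10), ncol = 2)
    randVals[s] <- min(rowSums(Xr^2))
  }
  expect_lt(median(besVals), median(randVals))
})
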