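test_that("herd initialization is uniform-in-bounds and seeded", {
  set.seed(2)
  X <- zoaInit(10, 5)
  expect_true(all(X >= 0 & X <= 1))
  set.seed(2)
  expect_identical(zoaInit(10, 5), X)
  # direct substitution: xmin + rand * (xmax - xmin)
  set.seed(4)
  r <- matrix(runif(4), 2, 2)
  set.seed(4)
  expect_equal(zoaInit(2, 2, 0, 10), 10 * r)
})

test_that("update and perturbation candidates match the scalar oracle", {
  set.seed(21)
  for (i in 1:20) {
    N <- sample(2:6, 1); d <- sample(1:4, 1)
    X <- matrix(rnorm(N * d), N, d)
    xBest <- rnorm(d); xAvg <- colMeans(X)
    u <- runif(N); g <- matrix(rnorm(N * d), N, d)
    c1 <- runif(1, 0.5, 1.5); c2 <- runif(1, 0.5, 1.5)
    sigma <- runif(d, 0, 0.3)
    expect_equal(zoaUpdateStep(X, xBest, xAvg, c1, c2, u),
                 oracleZoaUpdate(X, xBest, xAvg, c1, c2, u),
                 tolerance = 1e-8)
    expect_equal(zoaPerturbStep(X, sigma, g),
                 oracleZoaPerturb(X, sigma, g), tolerance = 1e-8)
  }
})

test_that("steps honour their closed-form special cases", {
  # c1 = c2 = 1, u = 0.5, X = 0, best = 4, avg = 2 -> 0 + 2 + 1 = 3
  expect_equal(drop(zoaUpdateStep(matrix(0), 4, 2, 1, 1, 0.5)), 3)
  # stationary at consensus
  X <- matrix(2, 4, 3)
  expect_equal(zoaUpdateStep(X, rep(2, 3), rep(2, 3), 1, 1, runif(4)), X)
  # zero disturbance leaves positions unchanged
  expect_identical(zoaPerturbStep(X, 0, matrix(rnorm(12), 4, 3)), X)
})

test_that("zoaMinimize clips to bounds and keeps a monotone trace", {
  seen <- new.env(); seen$bad <- FALSE
  obj <- function(x) {
    if (any(x < -1e-12 | x > 1 + 1e-12)) seen$bad <- TRUE
    sum((x - 0.25)^2)
  }
  out <- zoaMinimize(obj, dim = 3, control = zoaControl(N = 6, maxIter = 40),
                     seed = 3)
  expect_false(seen$bad)
  expect_true(all(diff(out$trace) <= 0))
  expect_lt(out$value, 1e-3)
  # deterministic under seed
  out2 <- zoaMinimize(obj, dim = 3, control = zoaControl(N = 6, maxIter = 40),
                      seed = 3)
  expect_identical(out$best, out2$best)
  # sigma = 0 on a converged herd is a fixed point of the update step
  Xc <- matrix(0.5, 5, 2)
  expect_equal(zoaUpdateStep(Xc, c(0.5, 0.5), c(0.5, 0.5), 1, 1, runif(5)),
               Xc)
})

test_that("perturbation lets a herd escape a higher well", {
  # two-well objective: local minimum at +1 (f = 0.2), global near -1
  f <- function(x) (x^2 - 1)^2 + 0.2 * x
  escapes <- 0L
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(1, 10, 1)  # herd parked in the higher well
    fit <- apply(X, 1, f)
    best <- X[which.min(fit), ]; bestFit <- min(fit)
    sigma <- 1
    for (iter in 1:50) {
      cand <- zoaUpdateStep(X, best, colMeans(X), 1, 1, runif(10))
      cand <- pmin(pmax(cand, -5), 5)
      fc <- apply(cand, 1, f)
      ok <- fc < fit; X[ok, ] <- cand[ok, ]; fit[ok] <- fc[ok]
      cand <- zoaPerturbStep(X, sigma, matrix(rnorm(10), 10, 1))
      cand <- pmin(pmax(cand, -5), 5)
      fc <- apply(cand, 1, f)
      ok <- fc < fit; X[ok, ] <- cand[ok, ]; fit[ok] <- fc[ok]
      if (min(fit) < bestFit) { bestFit <- min(fit); best <- X[which.min(fit), ] }
    }
    if (best < 0) escapes <- escapes + 1L
  }
  expect_gte(escapes, 8L)
})

test_that("positions decode inside the stated closed ranges", {
  sp <- hyperparameterSpace()
  # log-midpoint learning rate is exactly 1e-3
  expect_equal(decodePosition(rep(0.5, 5), sp)$learningRate, 1e-3,
               tolerance = 1e-15)
  # integer endpoints
  expect_identical(decodePosition(c(0, 0, 0, 0, 0), sp)$gruUnits, 32L)
  expect_identical(decodePosition(c(1, 1, 1, 1, 1), sp)$gruUnits, 256L)
  expect_identical(decodePosition(rep(0.5, 5), sp)$epochs, 55L)
  # fuzzed positions stay inside every closed range
  set.seed(77)
  for (i in 1:200) {
    cfg <- decodePosition(runif(5), sp)
    expect_true(cfg$learningRate >= 1e-4 && cfg$learningRate <= 1e-2)
    expect_true(cfg$gruUnits >= 32L && cfg$gruUnits <= 256L)
    expect_true(cfg$batchSize >= 16L && cfg$batchSize <= 128L)
    expect_true(cfg$dropout >= 0.1 && cfg$dropout <= 0.5)
    expect_true(cfg$epochs >= 10L && cfg$epochs <= 100L)
  }
})

test_that("the error-rate fitness is percent misclassified", {
  expect_equal(classifierErrorRate(rep(1, 100), c(rep(1, 95), rep(2, 5))), 5)
  expect_equal(classifierErrorRate(c("a", "b"), c("a", "b")), 0)
  expect_error(classifierErrorRate(1:3, 1:2), "mismatch")
})

test_that("tuning returns a monotone trace and beats random configurations", {
  d <- makePreprocessed(nPerClass = 40, D = 16, nInformative = 6, seed = 12)
  X <- featureValues(d$fm); y <- as.character(sampleLabels(d$fm))
  sp <- stratifiedSplit(y, 0.75, seed = 1)
  tuned <- tuneBiGRU(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                     control = zoaControl(N = 3, maxIter = 2), chunk = 8,
                     seed = 5)
  expect_true(all(diff(tuned$trace) <= 0))
  expect_true(all(c("learningRate", "gruUnits", "batchSize", "dropout",
                    "epochs") %in% names(tuned$best)))
  expect_gte(nrow(tuned$evaluated), 3L)
  # random baseline from the same space
  set.seed(50)
  randErr <- sapply(1:6, function(i) {
    cfg <- decodePosition(runif(5))
    m <- trainBiGRU(X[sp$train, ], y[sp$train], hidden = cfg$gruUnits,
                    chunk = 8, learningRate = cfg$learningRate,
                    batchSize = cfg$batchSize, dropout = cfg$dropout,
                    epochs = cfg$epochs, seed = 99)
    classifierErrorRate(y[sp$test], predict(m, X[sp$test, ]))
  })
  expect_lte(tuned$error, median(randErr))
})
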