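test_that("stratified split preserves proportions and the rounding contract", {
  # balanced 3-class design at the study scale: 70% of 6500 per class
  y <- rep(c("Plastic", "Peptide", "Oligosaccharide"), each = 6500)
  sp <- stratifiedSplit(y, 0.7, seed = 1)
  expect_identical(length(sp$train), 13650L)
  tab <- table(y[sp$train])
  expect_true(all(tab == 4550L))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  # 5/5 two-class at 0.7: total 7, each class 3 or 4
  y2 <- rep(c("a", "b"), each = 5)
  sp2 <- stratifiedSplit(y2, 0.7, seed = 2)
  expect_identical(length(sp2$train), 7L)
  expect_true(all(table(y2[sp2$train]) %in% c(3L, 4L)))
  # determinism and error on singleton classes
  expect_identical(stratifiedSplit(y2, 0.7, seed = 9),
                   stratifiedSplit(y2, 0.7, seed = 9))
  expect_error(stratifiedSplit(c("a", "a", "b"), 0.7), "2 members")
})

test_that("the worked binary confusion example is reproduced", {
  # confusion [[8,2],[1,9]] with rows = true class
  yTrue <- c(rep("neg", 10), rep("pos", 10))
  yPred <- c(rep("neg", 8), rep("pos", 2), "neg", rep("pos", 9))
  set.seed(1)
  pPos <- c(runif(8, 0, 0.4), runif(2, 0.6, 1), runif(1, 0, 0.4),
            runif(9, 0.6, 1))
  proba <- cbind(neg = 1 - pPos, pos = pPos)
  rep <- computeMetrics(yTrue, yPred, proba)
  expect_equal(rep@accuracy, 0.85)
  expect_equal(rep@perClass["neg", "precision"], 8 / 9, tolerance = 1e-10)
  expect_equal(rep@perClass["neg", "recall"], 0.8)
  expect_equal(rep@perClass["neg", "f1"], 0.8421, tolerance = 1e-4)
  expect_identical(rep@confusion["neg", "neg"], 8L)
  expect_identical(rep@confusion["pos", "neg"], 1L)
})

test_that("perfect and uninformative predictions hit their boundaries", {
  yTrue <- rep(c("a", "b", "c"), each = 4)
  proba <- matrix(0, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  proba[cbind(1:12, match(yTrue, c("a", "b", "c")))] <- 1
  rep <- computeMetrics(yTrue, yTrue, proba)
  expect_true(all(unlist(rep@perClass) == 1))
  expect_equal(unname(rep@macro), rep(1, 5))
  # uniform probabilities: midrank ties give AUC exactly 0.5
  pu <- matrix(1 / 3, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  repU <- computeMetrics(yTrue, yTrue, pu)
  expect_true(all(repU@perClass$auc == 0.5))
})

test_that("metrics agree with the brute-force double-loop implementation", {
  set.seed(33)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    n <- sample(8:30, 1)
    classes <- letters[1:k]
    yTrue <- sample(classes, n, replace = TRUE)
    while (length(unique(yTrue)) < k) yTrue <- sample(classes, n, replace = TRUE)
    yPred <- sample(classes, n, replace = TRUE)
    raw <- matrix(runif(n * k), n, k, dimnames = list(NULL, classes))
    # occasional exact ties exercise the midrank handling
    if (i %% 3 == 0) raw[sample(n, 2), ] <- 0.5
    proba <- raw / rowSums(raw)
    got <- computeMetrics(yTrue, yPred, proba)
    want <- bruteMetrics(yTrue, yPred, proba)
    for (cl in classes) {
      expect_identical(got@perClass[cl, "accuracy"], want[cl, "accuracy"])
      expect_identical(got@perClass[cl, "precision"], want[cl, "precision"])
      expect_identical(got@perClass[cl, "recall"], want[cl, "recall"])
      expect_equal(got@perClass[cl, "auc"], want[cl, "auc"],
                   tolerance = 1e-10)
    }
    expect_equal(unname(got@macro["f1"]), mean(want[, "f1"]),
                 tolerance = 1e-12)
  }
})

test_that("macro averages are invariant to class relabeling", {
  set.seed(12)
  yTrue <- sample(c("a", "b", "c"), 30, replace = TRUE)
  yTrue[1:3] <- c("a", "b", "c")
  yPred <- sample(c("a", "b", "c"), 30, replace = TRUE)
  raw <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  proba <- raw / rowSums(raw)
  r1 <- computeMetrics(yTrue, yPred, proba)
  perm <- c(a = "z", b = "m", c = "q")
  proba2 <- proba; colnames(proba2) <- perm[colnames(proba)]
  proba2 <- proba2[, sort(colnames(proba2))]
  r2 <- computeMetrics(perm[yTrue], perm[yPred], proba2)
  expect_equal(r1@macro, r2@macro, tolerance = 1e-12)
})

test_that("metric preconditions are enforced", {
  proba <- cbind(a = c(0.6, 0.6), b = c(0.4, 0.4))
  expect_error(computeMetrics(c("a", "a"), c("a", "b"), proba), "absent")
  bad <- cbind(a = c(0.6, 0.6), b = c(0.5, 0.4))
  expect_error(computeMetrics(c("a", "b"), c("a", "b"), bad), "sum to 1")
})

test_that("run comparison tabulates macro metrics", {
  yTrue <- rep(c("a", "b"), 10)
  proba <- cbind(a = rep(c(0.8, 0.3), 10), b = rep(c(0.2, 0.7), 10))
  r <- computeMetrics(yTrue, yTrue, proba)
  tab1 <- compareRuns(list(r), "only")
  expect_identical(nrow(tab1), 1L)
  expect_true("macroF1" %in% names(tab1))
  tab2 <- compareRuns(list(r, r), c("x", "y"))
  expect_equal(tab2[1, -1], tab2[2, -1], ignore_attr = TRUE)
  tabP <- compareRuns(list(r), "pct", percent = TRUE)
  expect_equal(tabP$macroF1, 100)
})
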