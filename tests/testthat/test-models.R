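test_that("KNN matches the exhaustive majority vote and its tie rule", {
  # one training point per class classifies itself
  x1 <- matrix(c(0, 5, 10), ncol = 1)
  f1 <- fitClassifier(x1, c("a", "b", "c"), classifierSpec("KNN", knnK = 1))
  expect_equal(as.character(predictClassifier(f1, x1)), c("a", "b", "c"))

  # crafted 1-D ten-point set against the brute-force vote
  set.seed(20)
  xt <- matrix(sort(runif(10, 0, 10)), ncol = 1)
  yt <- rep(c("a", "b"), 5)
  q <- matrix(runif(25, 0, 10), ncol = 1)
  fit <- fitClassifier(xt, yt, classifierSpec("KNN"))
  z <- attr(scale(xt), "scaled:center")
  got <- as.character(predictClassifier(fit, q))
  want <- oracleKnn(scale(xt), yt,
                    scale(q, center = mean(xt), scale = sd(xt)), 5)
  expect_equal(got, unname(want))
})

test_that("the decision tree grows to pure leaves on separable data", {
  set.seed(21)
  x <- matrix(c(rnorm(40, 0), rnorm(40, 6)), ncol = 2)
  y <- rep(c("p", "q"), each = 20)
  fit <- fitClassifier(x, y, classifierSpec("DT"))
  expect_equal(mean(as.character(predictClassifier(fit, x)) == y), 1)
  expect_error(fitClassifier(x, rep("p", 40), classifierSpec("DT")),
               "2 classes")
})

test_that("regressors honor their contracts on toy data", {
  set.seed(22)
  x <- matrix(runif(80), 20, 4)
  y <- x[, 1]
  # extra trees interpolate a noiseless training grid
  et <- fitRegressor(x, y, regressorSpec("ET"))
  expect_lt(sqrt(mean((predictRegressor(et, x) - y)^2)), 1e-6)
  # constant targets are reproduced by the tree families
  for (fam in c("DT", "ET", "RF", "GB", "AB")) {
    fit <- suppressMessages(fitRegressor(x, rep(2.5, 20), regressorSpec(fam)))
    expect_equal(unname(predictRegressor(fit, x)), rep(2.5, 20),
                 tolerance = 1e-8)
  }
  expect_error(fitRegressor(x, rep(1, 20), regressorSpec("GPR")),
               "degenerate")
  # every family trains and predicts finite values
  yr <- x[, 1] + 0.1 * rnorm(20)
  for (fam in c("XGB", "LGB", "SVM", "GPR")) {
    fit <- fitRegressor(x, yr, regressorSpec(fam))
    expect_true(all(is.finite(predictRegressor(fit, x))))
  }
})

test_that("gradient boosting's first stage equals the brute-force stump", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c(1, 1.2, 3, 3.4)
  gb <- fitRegressor(x, y, regressorSpec("GB", nTrees = 1L, maxDepth = 1L))
  st <- oracleStump(x, y - mean(y))
  want <- mean(y) + 0.1 * predictStump(st, x)  # shrinkage 0.1
  expect_equal(unname(predictRegressor(gb, x)), unname(want),
               tolerance = 1e-10)
})

test_that("weights bin into the volume groups with half-open bounds", {
  expect_equal(as.character(volumeGroup(3)), "low")
  expect_equal(as.character(volumeGroup(6)), "intermediate")
  expect_equal(as.character(volumeGroup(9)), "high")
  expect_equal(as.character(volumeGroup(4.5)), "intermediate")
  expect_equal(as.character(volumeGroup(7.5)), "high")
  expect_error(volumeGroup(NA_real_))
})

test_that("cascades route through their components", {
  set.seed(23)
  n <- 60
  mat <- rep(c("A", "B", "C"), each = n / 3)
  w <- rep(c(3, 6, 9), n / 3)
  x <- cbind(ifelse(mat == "A", 10, ifelse(mat == "B", 5, 0)) + rnorm(n, 0, 0.1),
             w + rnorm(n, 0, 0.1))
  for (ordering in c("classify_first", "regress_first")) {
    fit <- cascadeFit(x, mat, w, ordering,
                      classifierSpec("KNN"), regressorSpec("ET"))
    pr <- cascadePredict(fit, x)
    expect_gte(mean(as.character(pr$material) == mat), 0.95)
    expect_lt(sqrt(mean((pr$weight - w)^2)), 1)
  }
  # degenerate single-class cascade gives constant material
  deg <- cascadeFit(x[1:20, ], rep("A", 20), w[1:20], "classify_first",
                    classifierSpec("KNN"), regressorSpec("ET"))
  expect_equal(unique(cascadePredict(deg, x[1:5, ])$material), "A")
})

test_that("LM training solves linear problems to least-squares accuracy", {
  set.seed(24)
  X <- matrix(rnorm(200), 50, 4)
  y <- drop(X %*% c(2, -1, 0.5, 3)) + 1
  net <- trainFfnn(X, y, hidden = 5, epochs = 100,
                   hiddenActivation = "linear", outputActivation = "linear",
                   seed = 2)
  expect_lt(max(abs(predictFfnn(net, X) - fitted(lm(y ~ X)))), 1e-6)
  expect_true(all(diff(net$loss) <= 1e-9))
  net0 <- trainFfnn(X, y, hidden = 5, epochs = 0, seed = 2)
  expect_length(net0$loss, 1)
  init <- trainFfnn(X, y, hidden = 5, epochs = 0, seed = 2)
  expect_identical(net0$weights, init$weights)
})

test_that("Bayesian regularization shrinks weights and tracks evidence", {
  # alpha frozen at zero reduces BR to LM exactly
  set.seed(25)
  X <- matrix(rnorm(60), 20, 3)
  y <- drop(X %*% c(1, 2, -1))
  lmN <- trainFfnn(X, y, hidden = 4, epochs = 30,
                   hiddenActivation = "linear", outputActivation = "linear",
                   seed = 3)
  brN <- trainFfnnBr(X, y, hidden = 4, epochs = 30,
                     hiddenActivation = "linear", outputActivation = "linear",
                     seed = 3, alpha0 = 0, beta0 = 1, updateHyper = FALSE)
  expect_equal(brN$weights, lmN$weights, tolerance = 1e-8)

  # noisy small-sample toys: BR weight norm never exceeds LM's
  cmp <- sapply(1:20, function(s) {
    set.seed(s)
    Xs <- matrix(rnorm(60), 20, 3)
    ys <- rnorm(20)
    c(lm = sum(trainFfnn(Xs, ys, hidden = 8, epochs = 40,
                         seed = s)$weights^2),
      br = sum(trainFfnnBr(Xs, ys, hidden = 8, epochs = 40,
                           seed = s)$weights^2))
  })
  expect_true(all(cmp["br", ] <= cmp["lm", ] + 1e-9))

  # pure-noise targets: effective parameters far below the weight count
  set.seed(26)
  Xn <- matrix(rnorm(90), 30, 3)
  bn <- trainFfnnBr(Xn, rnorm(30), hidden = 8, epochs = 40, seed = 1)
  nw <- length(bn$weights)
  expect_lt(bn$gamma, nw / 3)
})

test_that("sip-volume regression handles informative and constant features", {
  set.seed(27)
  vols <- rep(c(10, 20, 30, 40), each = 10)
  x <- cbind(vols + rnorm(40, 0, 0.5), rnorm(40))
  fit <- sipVolumeRegress(x, vols, regressorSpec("NN", nnHidden = 10L,
                                                 nnEpochs = 50L,
                                                 nnTrainer = "BR"))
  m <- regressionMetrics(vols, predictRegressor(fit, x))
  expect_gte(m$r2, 0.95)
  cst <- suppressMessages(fitRegressor(matrix(1, 40, 2), vols,
                                       regressorSpec("ET")))
  expect_equal(unname(predictRegressor(cst, matrix(1, 5, 2))),
               rep(mean(vols), 5))
})
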