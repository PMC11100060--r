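test_that("fold plans partition samples and respect subject disjointness", {
  subj <- rep(sprintf("S%02d", 1:10), each = 12)
  for (seed in 1:5) {
    cs <- makeFolds(subj, "CS", k = 5, seed = seed)
    for (f in cs@folds) {
      expect_length(unique(subj[f$test]), 2)
      expect_length(intersect(subj[f$train], subj[f$test]), 0)
    }
    expect_setequal(unlist(lapply(cs@folds, `[[`, "test")),
                    seq_along(subj))
    as <- makeFolds(subj, "AS", k = 5, seed = seed)
    tests <- unlist(lapply(as@folds, `[[`, "test"))
    expect_equal(sort(tests), seq_along(subj))
    # every subject appears in both sides of every AS fold
    for (f in as@folds) {
      expect_setequal(unique(subj[f$train]), unique(subj))
      expect_setequal(unique(subj[f$test]), unique(subj))
    }
  }
  expect_error(makeFolds(rep("a", 10), "CS"), "at least k")
})

test_that("the 80-20 holdout reproduces the bites split arithmetic", {
  sp <- holdoutSplit(2340, frac = 0.8, seed = 1)
  expect_length(sp$train, 1872)
  expect_length(sp$test, 468)
  expect_setequal(c(sp$train, sp$test), 1:2340)
  # stratified variant keeps the per-subject ratio
  subj <- rep(c("u", "v"), each = 50)
  st <- holdoutSplit(subj, frac = 0.8, seed = 2)
  expect_equal(sum(subj[st$train] == "u"), 40)
})

test_that("classification metrics match hand arithmetic and brute force", {
  m <- classificationMetrics(c("a", "b"), c("a", "b"))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(100, 100, 100))
  # TP 9 FN 1 TN 8 FP 2 on the positive class
  truth <- c(rep("pos", 10), rep("neg", 10))
  pred <- c(rep("pos", 9), "neg", rep("neg", 8), rep("pos", 2))
  m2 <- classificationMetrics(truth, pred)
  expect_equal(m2$accuracy, 85)
  expect_equal(m2$perClass$sensitivity[m2$perClass$class == "pos"], 90)
  expect_equal(m2$perClass$specificity[m2$perClass$class == "pos"], 80)
  set.seed(30)
  for (i in 1:5) {
    t3 <- sample(c("x", "y", "z"), 60, TRUE)
    p3 <- sample(c("x", "y", "z"), 60, TRUE)
    got <- classificationMetrics(t3, p3)
    want <- oracleClassMetrics(t3, p3)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$sensitivity, tolerance = 1e-12)
    expect_equal(got$specificity, want$specificity, tolerance = 1e-12)
  }
  # class absent from truth is excluded from the macro mean
  m4 <- classificationMetrics(c("a", "a", "b"), c("a", "c", "b"))
  expect_false("c" %in%
                 m4$perClass$class[m4$perClass$present])
})

test_that("regression metrics match hand arithmetic and brute force", {
  m <- regressionMetrics(1:5, 1:5)
  expect_equal(c(m$rmse, m$mae, m$r2), c(0, 0, 1))
  m2 <- regressionMetrics(c(0, 0), c(3, 4))
  expect_equal(m2$rmse, sqrt(12.5))
  expect_equal(m2$mae, 3.5)
  set.seed(31)
  for (i in 1:5) {
    t <- rnorm(40); p <- rnorm(40)
    got <- regressionMetrics(t, p)
    want <- oracleRegMetrics(t, p)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
    expect_equal(got$mae, want$mae, tolerance = 1e-12)
    expect_equal(got$r2, want$r2, tolerance = 1e-12)
  }
  expect_warning(regressionMetrics(c(1, 1), c(1, 2)), "zero-variance")
})

test_that("experiments report every requested cell and are reproducible", {
  ft <- cohortFeatureTable(3, smallProtocol(), seed = 40)
  cfg <- list(nSubjects = 3, seed = 40, tasks = c("solid-type", "sip-volume"),
              schemes = "AS", classifiers = "KNN", regressor = "DT")
  r1 <- reportTable(runExperiment(cfg, features = ft))
  r2 <- reportTable(runExperiment(cfg, features = ft))
  expect_identical(r1, r2)
  cells <- unique(r1[, c("task", "model")])
  expect_setequal(paste(cells$task, cells$model),
                  c("solid-type KNN", "sip-volume DT"))
  expect_true(all(r1$accuracy[r1$task == "solid-type"] >= 0 &
                    r1$accuracy[r1$task == "solid-type"] <= 100))
})
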