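test_that("hand-computed values match the standard definitions", {
  f <- extractFeatures(c(1, -1, 2, -2))
  expect_length(f, 40)
  expect_identical(names(f), featureNames())
  expect_equal(unname(f["MAV"]), 1.5)
  expect_equal(unname(f["IEMG"]), 6)
  expect_equal(unname(f["SSI"]), 10)
  expect_equal(unname(f["RMS"]), sqrt(2.5))
  expect_equal(unname(f["WL"]), 9)

  g <- extractFeatures(rep(2, 50))
  expect_equal(unname(g[c("VAR", "ZC", "SSC", "WL")]), c(0, 0, 0, 0))
  expect_equal(unname(g[c("LCOV", "MFL", "LTKEO")]), c(-30, -30, -30))

  expect_equal(zeroCrossings(c(1, -1, 1, -1), 0), 3)
  expect_equal(zeroCrossings(c(1, 2, 3), 0), 0)
  expect_equal(willisonAmplitude(c(0, 1, 0, 1), 0.5), 3)
  expect_equal(willisonAmplitude(rnorm(20), Inf), 0)
  expect_equal(maximumFractalLength(c(0, 3, 0)), log10(sqrt(18)))
  expect_equal(maximumFractalLength(rep(1, 10)), -30)
  expect_error(extractFeatures(c(1, 2)), "short")
  expect_error(zeroCrossings(1), "2 samples")
})

test_that("the full forty-feature vector matches the brute-force reference", {
  set.seed(10)
  cfg <- featureConfig()
  for (i in 1:20) {
    n <- sample(100:600, 1)
    x <- rnorm(n, sd = runif(1, 0.05, 2))
    got <- extractFeatures(x, cfg)
    want <- oracleFeatures(x)[names(got)]
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("features scale as documented under a multiplicative gain", {
  set.seed(11)
  x <- rnorm(400, sd = 0.5)
  g <- 3.7
  cfg <- featureConfig(wampThreshold = 0, myopThreshold = 0)
  f1 <- extractFeatures(x, cfg)
  f2 <- extractFeatures(g * x, cfg)
  linear <- c("MAV", "IEMG", "RMS", "WL", "SD", "MAD", "IQR", "DAMV",
              "DASDV", "AAC")
  expect_equal(unname(f2[linear]), unname(g * f1[linear]), tolerance = 1e-9)
  quad <- c("SSI", "VAR", "AE", "VAREMG", "DVARV")
  expect_equal(unname(f2[quad]), unname(g^2 * f1[quad]), tolerance = 1e-9)
  counts <- c("ZC", "SSC", "WAMP", "MYOP", "NZC")
  expect_equal(unname(f2[counts]), unname(f1[counts]))
  dimless <- c("SKEW", "KURT", "COV", "AR1", "AR2")
  expect_equal(unname(f2[dimless]), unname(f1[dimless]), tolerance = 1e-9)
})

test_that("order-dependent features react to permutation, moments do not", {
  set.seed(12)
  x <- rnorm(300)
  p <- sample(x)
  f1 <- extractFeatures(x)
  f2 <- extractFeatures(p)
  for (nm in c("WL", "AAC", "SSC", "DAMV", "MFL", "DASDV"))
    expect_false(isTRUE(all.equal(f1[[nm]], f2[[nm]])))
  for (nm in c("MAV", "VAR", "SKEW", "KURT", "RMS", "IQR"))
    expect_equal(f1[[nm]], f2[[nm]])
})

test_that("the registry is complete and configuration-aware", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 40)
  expect_identical(reg$name, featureNames())
  cfg4 <- featureConfig(arOrder = 4)
  expect_length(featureNames(cfg4), 42)
  expect_length(extractFeatures(rnorm(100), cfg4), 42)
  expect_error(featureConfig(arOrder = 0))
})

test_that("featurized segments keep their labels", {
  prof <- testProfile()
  segs <- list(
    new("SwallowSegment", samples = synthSwallowBurst("A", 6, prof, 1),
        rate = 1000, mamClass = "high", subjectId = "T1", label = "A",
        amount = 6, startSample = 0, endSample = 100),
    new("SwallowSegment", samples = synthSwallowBurst("water", 20, prof, 2),
        rate = 1000, mamClass = "low", subjectId = "T1", label = "water",
        amount = 20, startSample = 200, endSample = 300))
  tab <- featurizeSegments(segs)
  expect_equal(dim(tab), c(2, 4 + 40))
  expect_equal(tab$label, c("A", "water"))
  expect_true(all(is.finite(as.matrix(tab[, featureNames()]))))
})
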