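test_that("the architecture audit matches the fixed design", {
  m <- buildSipCnn(4096L, seed = 1)
  tr <- architectureTrace(m)
  convs <- tr[grepl("^conv", tr$layer), ]
  expect_equal(convs$outChannels, c(32L, 32L, 32L, 64L, 64L))
  expect_true(all(grepl("batchnorm", convs$type)))
  pools <- tr[grepl("^pool", tr$layer), ]
  expect_equal(pools$outLength, c(2048L, 1024L, 512L, 256L, 128L))
  expect_equal(tr$outLength[tr$layer == "flatten"], 128L * 64L)
  expect_equal(tr$outLength[tr$layer == "output"], 4L)
  # kernel and parameter shapes
  expect_equal(m$kernel, 5L)
  expect_equal(dim(m$conv[[1]]$W), c(5L, 32L))
  expect_equal(dim(m$conv[[4]]$W), c(5L * 32L, 64L))
  expect_error(buildSipCnn(100L), "multiple of 32")
})

test_that("initialization and forward pass are deterministic", {
  m1 <- buildSipCnn(320L, seed = 9)
  m2 <- buildSipCnn(320L, seed = 9)
  expect_identical(m1$conv[[3]]$W, m2$conv[[3]]$W)
  expect_identical(m1$dense[[1]]$W, m2$dense[[1]]$W)
  m3 <- buildSipCnn(320L, seed = 10)
  expect_false(identical(m1$conv[[1]]$W, m3$conv[[1]]$W))
  set.seed(1)
  X <- matrix(rnorm(3 * 320), 3, 320)
  fw <- .cnnForward(m1, X, training = FALSE)
  expect_equal(dim(fw$logits), c(3L, 4L))
  expect_true(all(is.finite(fw$logits)))
})

test_that("segments are padded or resampled to the input length", {
  m <- buildSipCnn(320L, seed = 1)
  short <- sin(1:100)
  long <- sin(1:1000)
  X <- prepareSipInput(list(short, long), m)
  expect_equal(dim(X), c(2L, 320L))
  expect_equal(X[1, 1:100], short)           # right-padded with zeros
  expect_true(all(X[1, 101:320] == 0))
  expect_equal(X[2, c(1, 320)], long[c(1, 1000)])  # resampled endpoints
  mN <- buildSipCnn(320L, seed = 1, normalize = TRUE)
  XN <- prepareSipInput(list(short), mN)
  expect_equal(sqrt(mean(XN[1, 1:100]^2)), 1, tolerance = 1e-9)
})

test_that("training is seeded-deterministic and learns a separable toy", {
  set.seed(2)
  n <- 48
  labs <- rep(c(10, 20, 30, 40), n / 4)
  X <- t(vapply(labs, function(l) {
    on <- 16 + l * 6
    c(rnorm(on, 0, l / 5), rep(0, 320 - on))
  }, numeric(320)))
  m <- buildSipCnn(320L, seed = 3, denseUnits = c(16L, 8L))
  f1 <- trainSipCnn(m, X, labs, epochs = 3, seed = 4)
  f2 <- trainSipCnn(m, X, labs, epochs = 3, seed = 4)
  expect_identical(f1$conv[[5]]$W, f2$conv[[5]]$W)
  expect_identical(f1$history, f2$history)
  f3 <- trainSipCnn(m, X, labs, epochs = 25, seed = 4, lr = 3e-3)
  expect_gte(utils::tail(f3$history$accuracy, 1), 0.9)
  pred <- predictSipCnn(f3, X)
  expect_gte(mean(pred == labs), 0.9)
  expect_error(trainSipCnn(m, X, rep(15, n), epochs = 1), "labels")
})
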