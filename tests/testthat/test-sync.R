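# Sliding-window high-frequency ratio used as an independent check of the
# detector's score ordering.
peakHfRatio <- function(x, rate = 1000, win = 200) {
  hp <- signal::filtfilt(signal::butter(4, 200 / (rate / 2), "high"), x)
  starts <- seq(1, length(x) - win + 1, by = 50)
  max(sapply(starts, function(s) {
    i <- s:(s + win - 1)
    sum(hp[i]^2) / sum(x[i]^2)
  }))
}

test_that("interference detection recovers the injected window", {
  ok <- 0
  for (s in 1:8) {
    prof <- sampleSubjectProfile(paste0("Y", s), 100 + s)
    ses <- generateSession(prof, smallProtocol(), seed = 200 + s)
    w <- detectInterferenceWindow(emgTrace(ses), emgRate(ses))
    truth <- interferenceTruth(ses)
    inter <- max(0, min(w@endSample, truth[2]) - max(w@startSample, truth[1]))
    union <- max(w@endSample, truth[2]) - min(w@startSample, truth[1])
    expect_gte(inter / union, 0.5)
    expect_lte(abs(w@startSample - truth[1]), 50)
    ok <- ok + 1
  }
  expect_equal(ok, 8)
})

test_that("no interference is reported on clean signals", {
  # pure baseline noise
  set.seed(4)
  expect_null(detectInterferenceWindow(rnorm(60000, 0, 0.01), 1000))
  # a full injection-free session (bursts must not trigger the detector)
  prof <- testProfile()
  ses <- generateSession(prof, smallProtocol(), seed = 31, injectSync = FALSE)
  expect_null(detectInterferenceWindow(emgTrace(ses), emgRate(ses)))
  # the injected session scores above its pre-injection self
  inj <- injectInterference(ses, at = 2, duration = 0.5, seed = 8)
  w <- detectInterferenceWindow(emgTrace(inj), emgRate(inj))
  expect_gt(w@score, peakHfRatio(emgTrace(ses)))
  expect_error(detectInterferenceWindow(rnorm(100), 1000, windowLen = 200),
               "shorter")
})

test_that("excision bridges the window and preserves length", {
  set.seed(2)
  x <- rnorm(5000)
  w <- new("ChangeWindow", startSample = 1000, endSample = 1500, score = 1)
  y <- exciseWindow(x, w)
  expect_length(y, length(x))
  expect_identical(y[-(1001:1500)], x[-(1001:1500)])
  # bridged region is the straight segment between the boundary samples
  expect_equal(y[1001:1500],
               seq(x[1000], x[1501], length.out = 502)[-c(1, 502)])
  # high-frequency energy cannot increase
  hp <- function(v) sum(highpass(v, 1000, 200)[1001:1500]^2)
  expect_lte(hp(y), hp(x))
  # degenerate full-signal window: straight line between the endpoints
  full <- exciseWindow(x, new("ChangeWindow", startSample = 0,
                              endSample = length(x), score = 1))
  expect_lte(max(abs(diff(diff(full[2:(length(x) - 1)])))), 1e-9)
  expect_error(exciseWindow(x, new("ChangeWindow", startSample = 0,
                                   endSample = 6000, score = 1)), "outside")
})

test_that("alignment maps the anchors exactly and recovers the true offset", {
  w <- new("ChangeWindow", startSample = 2000, endSample = 2500, score = 1)
  expect_equal(alignStreams(w, 2.0, 1000)@offset, 0)
  expect_error(alignStreams(NULL, 2.0), "anchor")
  expect_error(alignStreams(w, NA_real_), "anchor")

  errs <- sapply(1:5, function(s) {
    prof <- sampleSubjectProfile(paste0("Z", s), 300 + s)
    ses <- generateSession(prof, smallProtocol(), seed = 400 + s)
    sy <- syncSession(ses)
    abs(sy$alignment@offset - prof@anchorOffset)
  })
  expect_true(all(errs <= 0.05))

  # aligning an already-aligned wrist stream is idempotent
  prof <- sampleSubjectProfile("Z9", 77)
  ses <- generateSession(prof, smallProtocol(), seed = 78)
  sy <- syncSession(ses)
  shifted <- ses
  shifted@wiTime <- ses@wiTime + sy$alignment@offset
  a2 <- alignStreams(sy$window,
                     wiAnchorTime(shifted@wiTime, shifted@wi),
                     emgRate(ses))
  expect_lt(abs(a2@offset), 0.05)
})
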