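test_that("burst amplitude and duration grow with amount and hardness", {
  prof <- testProfile()
  seeds <- 1:30
  stat <- function(material, amount) {
    m <- sapply(seeds, function(s) {
      b <- synthSwallowBurst(material, amount, prof, seed = s)
      c(mav = mean(abs(b)), dur = length(b))
    })
    rowMeans(m)
  }
  a3 <- stat("A", 3); a9 <- stat("A", 9); c3 <- stat("C", 3)
  expect_gt(a9["mav"], a3["mav"])
  expect_gt(a9["dur"], a3["dur"])
  # softer material at equal amount: lower envelope peak
  pkA <- mean(sapply(seeds, function(s)
    max(emgEnvelope(synthSwallowBurst("A", 3, prof, s), 1000))))
  pkC <- mean(sapply(seeds, function(s)
    max(emgEnvelope(synthSwallowBurst("C", 3, prof, s), 1000))))
  expect_gt(pkA, pkC)
  # sips: rectified amplitude and duration grow with volume
  s10 <- stat("water", 10); s40 <- stat("water", 40)
  expect_gt(s40["mav"], s10["mav"])
  expect_gt(s40["dur"], s10["dur"])
})

test_that("bursts are zero-mean, deterministic under a seed, and validated", {
  prof <- testProfile()
  b1 <- synthSwallowBurst("B", 6, prof, seed = 7)
  b2 <- synthSwallowBurst("B", 6, prof, seed = 7)
  expect_identical(b1, b2)
  expect_lt(abs(mean(b1)), 1e-12)
  expect_false(identical(b1, synthSwallowBurst("B", 6, prof, seed = 8)))
  expect_error(synthSwallowBurst("D", 6, prof, 1), "unknown material")
  expect_error(synthSwallowBurst("A", -2, prof, 1), "positive")
})

test_that("wrist trace honors the activity angle bands", {
  prof <- testProfile()
  sip <- data.frame(kind = "sip", material = "water", amount = 20,
                    onset = 3, offset = 6)
  wt <- synthWiTrace(sip, prof, 10, seed = 1)
  inEv <- wt$time >= 3 & wt$time < 6
  expect_true(all(wt$angles[inEv, 1] >= 300 & wt$angles[inEv, 1] <= 350))
  expect_true(all(wt$angles[inEv, 2] >= 1 & wt$angles[inEv, 2] <= 60))

  bite <- data.frame(kind = "bite", material = "A", amount = 6,
                     onset = 3, offset = 6)
  wb <- synthWiTrace(bite, prof, 10, seed = 1)
  inEv <- wb$time >= 3 & wb$time < 6
  expect_true(all(wb$angles[inEv, 1] >= 200 & wb$angles[inEv, 1] <= 300))
  expect_true(all(wb$angles[inEv, 2] >= 90 & wb$angles[inEv, 2] <= 150))

  # no events: nothing in either activity band on X or Y
  none <- synthWiTrace(sip[0, ], prof, 10, seed = 2)
  expect_false(any(none$angles[, 1] >= 200 & none$angles[, 1] <= 350))
  expect_false(any(none$angles[, 2] >= 1 & none$angles[, 2] <= 150))

  over <- rbind(sip, data.frame(kind = "sip", material = "water",
                                amount = 10, onset = 5, offset = 8))
  expect_error(synthWiTrace(over, prof, 10, seed = 1), "overlap")
})

test_that("interference injection is local, seeded and spectrally high", {
  prof <- testProfile()
  ses <- generateSession(prof, smallProtocol(), seed = 3, injectSync = FALSE)
  inj <- injectInterference(ses, at = 2, duration = 0.5, seed = 11)
  d <- emgTrace(inj) - emgTrace(ses)
  expect_true(all(d[-(2001:2500)] == 0))
  expect_true(any(d[2001:2500] != 0))
  expect_identical(interferenceTruth(inj), c(2000, 2500))

  z <- injectInterference(ses, at = 2, duration = 0.5, amplitude = 0)
  expect_identical(emgTrace(z), emgTrace(ses))
  expect_identical(interferenceTruth(z), c(2000, 2500))

  centroid <- function(x) {
    p <- Mod(stats::fft(x - mean(x)))[1:(length(x) %/% 2)]^2
    f <- seq_len(length(p)) / length(x) * 1000
    sum(f * p) / sum(p)
  }
  expect_gt(centroid(emgTrace(inj)[2001:2500]),
            centroid(emgTrace(inj)[4001:4500]))

  expect_error(injectInterference(ses, at = -1, duration = 0.5), "outside")
  expect_error(injectInterference(ses, at = 2, duration = -1), "positive")
})

test_that("sessions follow the protocol event arithmetic", {
  prof <- testProfile()
  ses <- generateSession(prof, IngestProtocol(), seed = 5, signals = FALSE)
  ev <- sessionEvents(ses)
  expect_equal(nrow(ev), 85)
  sips <- ev[ev$kind == "sip", ]
  expect_equal(unname(as.vector(table(sips$amount))), rep(10L, 4))
  bites <- ev[ev$kind == "bite", ]
  expect_equal(unname(as.vector(table(bites$material, bites$amount))),
               rep(5L, 9))
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(utils::head(ev$offset, -1) < utils::tail(ev$onset, -1)))
})

test_that("cohorts are reproducible and sized correctly", {
  expect_identical(generateCohort(0, seed = 1), list())
  expect_error(generateCohort(-1, seed = 1), ">= 0")
  c1 <- generateCohort(3, smallProtocol(), seed = 9)
  c2 <- generateCohort(3, smallProtocol(), seed = 9)
  expect_identical(lapply(c1, emgTrace), lapply(c2, emgTrace))
  expect_identical(lapply(c1, sessionEvents), lapply(c2, sessionEvents))
  ids <- vapply(c1, function(s) subjectProfile(s)@subjectId, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  gains <- vapply(c1, function(s) subjectProfile(s)@emgGain, numeric(1))
  expect_gt(stats::sd(gains), 0)
})

test_that("sessions survive a CSV round trip", {
  prof <- testProfile()
  ses <- generateSession(prof, smallProtocol(), seed = 13)
  dir <- withr::local_tempdir()
  writeSessionCsv(ses, dir)
  expect_true(all(file.exists(file.path(dir, c("emg.csv", "wi.csv",
                                               "events.csv", "meta.json")))))
  back <- readSessionCsv(dir)
  expect_equal(emgTrace(back), emgTrace(ses), tolerance = 1e-12)
  expect_equal(sessionEvents(back)$onset, sessionEvents(ses)$onset,
               tolerance = 1e-12)
  expect_equal(interferenceTruth(back), interferenceTruth(ses))
  expect_equal(subjectProfile(back)@emgGain, subjectProfile(ses)@emgGain)
})
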