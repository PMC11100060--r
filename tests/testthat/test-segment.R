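test_that("calibration learns the generator's angle bands", {
  prof <- testProfile()
  cal <- generateCalibration(prof, seed = 3)
  th <- calibrateThresholds(cal$angles, cal$labels)
  expect_gte(th@ranges$drink[1, 1], 295)
  expect_lte(th@ranges$drink[2, 1], 355)
  # re-substitution agreement on separable calibration data
  pred <- predict(th@tree, data.frame(x = cal$angles[, 1],
                                      y = cal$angles[, 2],
                                      z = cal$angles[, 3]), type = "class")
  expect_gte(mean(as.character(pred) == as.character(cal$labels)), 0.99)
  # swapped labels swap the learned ranges
  swapped <- factor(c(drink = "eat", eat = "drink",
                      rest = "rest")[as.character(cal$labels)])
  th2 <- calibrateThresholds(cal$angles, swapped)
  expect_equal(th2@ranges$eat, th@ranges$drink)
  expect_equal(th2@ranges$drink, th@ranges$eat)
  expect_error(calibrateThresholds(cal$angles,
                                   rep("drink", nrow(cal$angles))),
               "both activities")
})

test_that("a separable two-axis toy set is reproduced exactly", {
  set.seed(6)
  n <- 300
  lab <- rep(c("drink", "eat", "rest"), each = n)
  ang <- rbind(cbind(runif(n, 310, 340), runif(n, 10, 50), runif(n, 15, 45)),
               cbind(runif(n, 210, 290), runif(n, 95, 145), runif(n, 65, 95)),
               cbind(runif(n, 40, 110), runif(n, 180, 230), runif(n, 120, 170)))
  th <- calibrateThresholds(ang, lab)
  pred <- classifyAngles(ang, th)
  expect_equal(mean(pred == lab), 1)
})

test_that("activity periods are recovered with high overlap", {
  prof <- testProfile()
  ses <- generateSession(prof, smallProtocol(), seed = 21)
  cal <- generateCalibration(prof, seed = 1)
  th <- calibrateThresholds(cal$angles, cal$labels)
  sy <- syncSession(ses)
  per <- detectActivityPeriods(sy$session@wiTime, sy$session@wi, th,
                               minDuration = 0.6)
  ev <- sessionEvents(ses)
  expect_equal(nrow(per), nrow(ev))
  ious <- sapply(seq_len(nrow(ev)), function(i) {
    ps <- per$start + sy$alignment@offset
    pe <- per$end + sy$alignment@offset
    inter <- pmin(pe, ev$offset[i]) - pmax(ps, ev$onset[i])
    j <- which.max(inter)
    act <- if (ev$kind[i] == "sip") "drinking" else "eating"
    if (per$activity[j] != act) return(0)
    inter[j] / (max(pe[j], ev$offset[i]) - min(ps[j], ev$onset[i]))
  })
  expect_gte(mean(ious >= 0.8), 0.95)

  # rest-only series yields nothing
  none <- synthWiTrace(ev[0, ], prof, 20, seed = 2)
  expect_equal(nrow(detectActivityPeriods(none$time, none$angles, th)), 0)

  # duration filter: a 3 s sip cannot pass a 5 s minimum
  one <- synthWiTrace(data.frame(kind = "sip", material = "water",
                                 amount = 20, onset = 5, offset = 8),
                      prof, 20, seed = 3)
  expect_equal(nrow(detectActivityPeriods(one$time, one$angles, th,
                                          minDuration = 5)), 0)
})

test_that("period mapping onto the sEMG clock is exact and clipped", {
  per <- data.frame(start = 2, end = 3, activity = "drinking")
  al <- new("StreamAlignment", offset = 0, emgRate = 1000)
  m <- mapToEmg(per, al, 10000)
  expect_equal(c(m$startSample, m$endSample), c(2000, 3000))
  al2 <- new("StreamAlignment", offset = -1, emgRate = 1000)
  m2 <- mapToEmg(per, al2, 10000)
  expect_equal(c(m2$startSample, m2$endSample), c(1000, 2000))
  expect_warning(m3 <- mapToEmg(per, al, 2500), "clipped")
  expect_equal(m3$endSample, 2500)
  expect_error(mapToEmg(data.frame(start = 20, end = 30,
                                   activity = "eating"), al, 2500),
               "outside")
})

test_that("MAM classification separates bites from sips", {
  expect_equal(classifyMam(rep(0, 1000), referenceLow = 0.1), "low")
  prof <- testProfile()
  ref <- stats::median(emgEnvelope(
    synthSwallowBurst("water", 20, prof, seed = 1), 1000))
  hits <- sapply(1:20, function(s) {
    bite <- synthSwallowBurst("C", 3, prof, seed = s)
    sip <- synthSwallowBurst("water", 40, prof, seed = s)
    c(classifyMam(bite, ref) == "high", classifyMam(sip, ref) == "low")
  })
  expect_gte(mean(hits), 0.95)
  # monotone in scale: doubling a high segment keeps it high
  b <- synthSwallowBurst("A", 9, prof, seed = 1)
  expect_equal(classifyMam(2 * b, ref), "high")
  expect_error(classifyMam(numeric(0), ref), "empty")
})

test_that("event splitting isolates one complex per activity interval", {
  prof <- testProfile()
  ses <- generateSession(prof, smallProtocol(), seed = 33)
  res <- segmentSession(ses)
  ev <- sessionEvents(ses)
  expect_gte(length(res$segments), nrow(ev) * 0.95)
  expect_lte(length(res$segments), nrow(ev) * 1.05)
  m <- matchEvents(ses, res$segments)
  expect_gte(mean(m$matched), 0.9)
  # no segment crosses its activity-interval boundary (with padding)
  pads <- 0.3 * emgRate(ses)
  for (g in res$segments) {
    inside <- any(res$intervals$startSample - pads <= g@startSample &
                    res$intervals$endSample + pads >= g@endSample)
    expect_true(inside)
  }
  # flat interval yields no segments
  flat <- splitEvents(rep(0, 5000),
                      data.frame(startSample = 1000, endSample = 4000,
                                 activity = "drinking"),
                      referenceLow = 0.01)
  expect_length(flat, 0)
  # determinism
  res2 <- segmentSession(ses)
  expect_equal(vapply(res$segments, function(g) g@startSample, numeric(1)),
               vapply(res2$segments, function(g) g@startSample, numeric(1)))
})
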