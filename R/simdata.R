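## Synthetic cohort generator.
##
## Emulates the study protocol: per subject, 40 water sips (10 each of
## 10/20/30/40 ml) and 45 solid boluses (5 each of 3 materials x 3/6/9 g),
## recorded as a 1 kHz single-channel neck sEMG trace plus a 1 kHz 3-axis
## wrist tilt-angle trace, with ground-truth event labels, a synchronization
## interference window near the session start, and talking activity in some
## inter-event gaps.

## Generator constants (see the methods vignette for rationale).  Amplitudes
## are envelope standard deviations in mV before the subject gain.
.sq <- list(
  solidBase   = c(A = 3.4, B = 1.85, C = 1.0),   # hard > intermediate > soft
  solidAmpF   = function(g)  0.8 + g / 30,        # mild amplitude growth
  solidDur    = function(g)  0.8 + g / 20,        # swallow-burst seconds
  nChews      = function(g)  round(4 + g),        # chew train length
  chewRate    = c(A = 1.1, B = 1.55, C = 2.1),    # Hz; harder = slower chews
  chewDuty    = 0.8,                              # chew burst fraction of period
  chewAmpF    = c(A = 0.75, B = 0.55, C = 0.38),  # chew amp vs swallow amp
  chewPause   = 0.15,                             # pause before final swallow
  sipBase     = 0.30,
  sipAmpF     = function(ml) 0.7 + 0.0125 * ml,
  sipDur      = function(ml) 1.0 + 0.025 * ml,
  ampJitterSd = 0.04,                             # per-burst lognormal jitter
  talkAmpF    = 0.3,                              # of the smallest sip amplitude
  interfAt    = 2.0, interfDur = 0.5, interfAmp = 2.0,
  gestureRise = 0.04, gestureFall = 0.4, gestureDeg = 80,
  rampSec     = 0.25,                             # wrist-angle transition ramp
  minGap      = 1.6, tStart = 10, tTail = 3,
  drinkAngles = rbind(lo = c(300, 1, 10),  hi = c(350, 60, 50)),
  eatAngles   = rbind(lo = c(200, 90, 60), hi = c(300, 150, 100)),
  restAngles  = rbind(lo = c(30, 170, 110), hi = c(120, 240, 175))
)

.sipAmp <- function(ml, gain) .sq$sipBase * .sq$sipAmpF(ml) * gain
.solidAmp <- function(material, g, gain)
  .sq$solidBase[[material]] * .sq$solidAmpF(g) * gain

## Total burst duration in seconds for an event, matching synthSwallowBurst.
burstDurationSec <- function(material, amount, profile) {
  if (material == "water") {
    .sq$sipDur(amount) * profile@durGain
  } else {
    ((.sq$nChews(amount) - 1 + .sq$chewDuty) / .sq$chewRate[[material]] +
       .sq$chewPause + .sq$solidDur(amount)) * profile@durGain
  }
}

#' Synthesize one swallow burst
#'
#' Produces a zero-mean sEMG burst as an amplitude-modulated band-limited
#' (20-450 Hz) Gaussian-noise carrier.  Sip bursts carry a single trapezoidal
#' swallow envelope; bite bursts carry a chew train (about 1.5 Hz envelope
#' bursts, count growing with bolus weight) followed by the swallow burst.
#' Envelope amplitude grows strictly with material hardness (A > B > C at
#' fixed amount) and both amplitude and total duration grow strictly with the
#' amount at fixed material; everything scales with the subject's sEMG gain.
#'
#' @param material "water", "A" (carrot), "B" (cheese) or "C" (banana).
#' @param amount sip volume in ml (water) or bolus weight in g (solids).
#' @param profile a [SubjectProfile-class].
#' @param seed RNG seed; identical arguments give identical samples.
#' @param rate sampling rate in Hz.
#' @return Numeric vector of sEMG samples (mV).
#' @export
synthSwallowBurst <- function(material, amount, profile, seed, rate = 1000) {
  if (!material %in% c("water", "A", "B", "C"))
    stop("unknown material: ", material)
  if (!is.finite(amount) || amount <= 0) stop("amount must be positive")
  dg <- profile@durGain
  n <- round(burstDurationSec(material, amount, profile) * rate)
  withSeed(seed, {
    if (material == "water") {
      env <- trapezoidEnvelope(n) * .sipAmp(amount, profile@emgGain)
    } else {
      amp <- .solidAmp(material, amount, profile@emgGain)
      env <- numeric(n)
      nch <- .sq$nChews(amount)
      per <- round(dg * rate / .sq$chewRate[[material]])
      chewLen <- round(per * .sq$chewDuty)
      for (i in seq_len(nch)) {
        i0 <- (i - 1L) * per
        idx <- i0 + seq_len(min(chewLen, n - i0))
        env[idx] <- sin(pi * seq_along(idx) / length(idx))^2 *
          amp * .sq$chewAmpF[[material]]
      }
      sw0 <- (nch - 1L) * per + chewLen + round(.sq$chewPause * dg * rate)
      swLen <- min(round(.sq$solidDur(amount) * dg * rate), n - sw0)
      env[sw0 + seq_len(swLen)] <- trapezoidEnvelope(swLen) * amp
    }
    env <- env * stats::rlnorm(1, 0, .sq$ampJitterSd)
    x <- bandlimitedNoise(n, rate, profile@emgBand[1], profile@emgBand[2]) * env
    x - mean(x)
  })
}

#' Synthesize a 3-axis wrist tilt-angle trace
#'
#' Inside sip events the X/Y angles stay within the drinking bands
#' (X in [300, 350], Y in [1, 60]); inside bite events within the eating
#' bands (X in [200, 300], Y in [90, 150]).  Outside events the angles wander
#' slowly in a rest band disjoint from both activity bands.  Short linear
#' ramps (default 0.25 s) connect the bands immediately before/after each
#' event; set `rampSec = 0` for step transitions.  An optional
#' synchronization "wrist flick" transient (a sharp X-angle ramp) can be
#' placed at `gestureAt` seconds.
#'
#' @param events data.frame(kind, material, amount, onset, offset), sorted and
#'   non-overlapping, times in seconds.
#' @param profile a [SubjectProfile-class] (supplies the angle bands).
#' @param duration trace duration, seconds.
#' @param seed RNG seed.
#' @param rate sampling rate, Hz.
#' @param rampSec transition ramp length, seconds.
#' @param gestureAt optional time (s) of the synchronization transient.
#' @return list(time, angles): time in seconds (session clock), angles an
#'   n x 3 matrix (X, Y, Z) in degrees.
#' @export
synthWiTrace <- function(events, profile, duration, seed, rate = 1000,
                         rampSec = .sq$rampSec, gestureAt = NULL) {
  if (nrow(events)) {
    if (any(events$offset <= events$onset)) stop("events must have offset > onset")
    if (is.unsorted(events$onset) ||
        any(utils::head(events$offset, -1) > utils::tail(events$onset, -1)))
      stop("events must be sorted and non-overlapping")
    if (any(events$offset > duration)) stop("events must lie within duration")
  }
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1L) / rate
  withSeed(seed, {
    ang <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    ## rest wander: low-frequency noise around the rest-band centre
    nk <- max(4L, ceiling(duration / 2))
    for (j in 1:3) {
      lo <- profile@restAngles[1, j]; hi <- profile@restAngles[2, j]
      ctr <- (lo + hi) / 2
      knots <- stats::rnorm(nk, 0, (hi - lo) / 8)
      w <- stats::approx(seq(0, duration, length.out = nk), knots, xout = tt)$y
      ang[, j] <- pmin(pmax(ctr + w, lo), hi)
    }
    for (i in seq_len(nrow(events))) {
      band <- if (events$kind[i] == "sip") profile@drinkAngles else
        profile@eatAngles
      i0 <- round(events$onset[i] * rate) + 1L
      i1 <- min(round(events$offset[i] * rate), n)
      if (i1 < i0) next
      for (j in 1:3) {
        lo <- band[1, j]; hi <- band[2, j]
        m <- 0.1 * (hi - lo)
        ctr <- stats::runif(1, lo + 2 * m, hi - 2 * m)
        jit <- movingAverage(stats::rnorm(i1 - i0 + 1L, 0, 3 * m), rate %/% 4)
        v <- pmin(pmax(ctr + jit, lo), hi)
        pre <- ang[i0, j]; post <- if (i1 < n) ang[min(i1 + 1L, n), j] else v[length(v)]
        ang[i0:i1, j] <- v
        nr <- round(rampSec * rate)
        if (nr > 0) {
          r0 <- max(1L, i0 - nr)
          if (r0 < i0)
            ang[r0:(i0 - 1L), j] <- seq(ang[r0, j], v[1], length.out = i0 - r0 + 1L)[-(i0 - r0 + 1L)]
          r1 <- min(n, i1 + nr)
          if (r1 > i1)
            ang[(i1 + 1L):r1, j] <- seq(v[length(v)], ang[r1, j], length.out = r1 - i1 + 1L)[-1L]
        }
      }
    }
    if (!is.null(gestureAt)) {
      g0 <- round(gestureAt * rate) + 1L
      nrise <- round(.sq$gestureRise * rate)
      nfall <- round(.sq$gestureFall * rate)
      shape <- c(seq(0, 1, length.out = nrise), seq(1, 0, length.out = nfall))
      idx <- g0 + seq_along(shape) - 1L
      keep <- idx <= n
      ang[idx[keep], 1] <- ang[idx[keep], 1] + .sq$gestureDeg * shape[keep]
    }
    list(time = tt, angles = ang)
  })
}

#' Inject a high-frequency interference window into a session's sEMG
#'
#' Adds a broadband 200-500 Hz component inside the window only (all other
#' samples are bit-identical) and records the window as the session's
#' interference ground truth.
#'
#' @param session a [SessionRecording-class] with a non-empty sEMG trace.
#' @param at window start, seconds.
#' @param duration window length, seconds (> 0).
#' @param amplitude interference amplitude (mV standard deviation).
#' @param seed RNG seed.
#' @return The modified [SessionRecording-class].
#' @export
injectInterference <- function(session, at, duration, amplitude = .sq$interfAmp,
                               seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  rate <- session@emgRate
  i0 <- round(at * rate)
  i1 <- round((at + duration) * rate)
  if (i0 < 0 || i1 > length(session@emg))
    stop("interference window outside the session")
  if (amplitude > 0) {
    comp <- withSeed(seed, bandlimitedNoise(i1 - i0, rate, 200, rate / 2 * 0.99))
    session@emg[(i0 + 1L):i1] <- session@emg[(i0 + 1L):i1] + comp * amplitude
  }
  session@interferenceTruth <- c(i0, i1)
  session
}

#' Draw a subject profile from the cohort variability model
#'
#' Inter-subject variability: lognormal sEMG gain (sd 0.3), lognormal event
#' pace (sd 0.15), baseline noise sd uniform in 0.008-0.015 mV, a
#' subject-specific burst carrier band (upper edge uniform in 260-440 Hz,
#' the spectral signature that separates subjects), and a uniform +/- 5 s
#' offset between the two sensor clocks.
#'
#' @param subjectId identifier.
#' @param seed RNG seed.
#' @return A [SubjectProfile-class].
#' @export
sampleSubjectProfile <- function(subjectId, seed) {
  withSeed(seed, new("SubjectProfile",
    subjectId = as.character(subjectId),
    emgGain = stats::rlnorm(1, 0, 0.3),
    durGain = stats::rlnorm(1, 0, 0.15),
    noiseSd = stats::runif(1, 0.008, 0.015),
    emgBand = c(20, stats::runif(1, 260, 440)),
    drinkAngles = .sq$drinkAngles,
    eatAngles = .sq$eatAngles,
    restAngles = .sq$restAngles,
    anchorOffset = stats::runif(1, -5, 5)
  ))
}

#' Generate one synthetic recording session
#'
#' Schedules the protocol's events (40 sips + 45 boluses under defaults) in
#' shuffled order with randomized inter-event gaps, synthesizes the sEMG and
#' wrist-angle streams, inserts low-amplitude talking bursts (30 % of the
#' smallest sip amplitude, no wrist activity) into some gaps, and injects the
#' synchronization interference window (with its simultaneous wrist-flick
#' transient) near the session start.  If the nominal protocol duration
#' cannot hold all events with the minimum gap, the session is extended just
#' enough to fit; event counts never change.
#'
#' @param profile a [SubjectProfile-class].
#' @param protocol an [IngestProtocol-class].
#' @param seed RNG seed; the session is fully reproducible from it.
#' @param signals if FALSE, only the event schedule is generated (empty
#'   streams); useful for protocol-arithmetic checks on large cohorts.
#' @param injectSync inject the synchronization interference window (and its
#'   wrist transient); FALSE gives an injection-free session.
#' @return A [SessionRecording-class].
#' @export
generateSession <- function(profile, protocol = IngestProtocol(), seed = 1L,
                            signals = TRUE, injectSync = TRUE) {
  validObject(protocol)
  seeds <- childSeeds(seed, 6)
  ## -- event schedule ------------------------------------------------------
  sips <- expand.grid(amount = protocol@sipVolumes,
                      rep = seq_len(protocol@nSipsPerVolume))
  bites <- expand.grid(material = protocol@materials,
                       amount = protocol@weights,
                       rep = seq_len(protocol@nBolusesPerCell),
                       stringsAsFactors = FALSE)
  ev <- rbind(
    data.frame(kind = "sip", material = "water", amount = sips$amount),
    data.frame(kind = "bite", material = bites$material, amount = bites$amount)
  )
  nEv <- nrow(ev)
  ev <- withSeed(seeds[1], ev[sample.int(nEv), , drop = FALSE])
  dur <- vapply(seq_len(nEv), function(i)
    burstDurationSec(ev$material[i], ev$amount[i], profile), numeric(1))
  required <- .sq$tStart + sum(dur) + nEv * .sq$minGap + .sq$tTail
  duration <- max(protocol@durationSec, ceiling(required))
  avail <- duration - .sq$tStart - sum(dur) - .sq$tTail
  u <- withSeed(seeds[2], stats::runif(nEv, 0.5, 1.5))
  gaps <- .sq$minGap + u / sum(u) * (avail - nEv * .sq$minGap)
  onset <- .sq$tStart + cumsum(gaps) + c(0, cumsum(dur)[-nEv])
  ev$onset <- onset
  ev$offset <- onset + dur
  rownames(ev) <- NULL
  if (!signals) {
    return(new("SessionRecording", subject = profile, emg = numeric(),
               emgRate = protocol@emgRate,
               wi = matrix(numeric(), 0, 3), wiTime = numeric(),
               wiRate = protocol@wiRate, events = ev,
               interferenceTruth = numeric(), duration = duration))
  }
  ## -- sEMG stream ---------------------------------------------------------
  rate <- protocol@emgRate
  n <- round(duration * rate)
  emg <- withSeed(seeds[4], stats::rnorm(n, 0, profile@noiseSd))
  bseeds <- childSeeds(seeds[3], 2L * nEv)
  for (i in seq_len(nEv)) {
    b <- synthSwallowBurst(ev$material[i], ev$amount[i], profile,
                           seed = bseeds[i], rate = rate)
    i0 <- round(ev$onset[i] * rate)
    idx <- i0 + seq_along(b)
    keep <- idx <= n
    emg[idx[keep]] <- emg[idx[keep]] + b[keep]
  }
  ## talking bursts in some wide gaps (wrist stays in the rest band)
  talkAmp <- .sq$talkAmpF * .sipAmp(min(protocol@sipVolumes), profile@emgGain)
  gapStart <- c(.sq$tStart, ev$offset)
  gapEnd <- c(ev$onset, duration - .sq$tTail)
  for (i in seq_along(gapStart)) {
    g <- gapEnd[i] - gapStart[i]
    if (g <= 2.2) next
    s <- bseeds[nEv + min(i, nEv)]
    talk <- withSeed(s + 7L, {
      if (stats::runif(1) > 0.3) NULL else {
        d <- min(1.5, g - 1.4)
        list(at = gapStart[i] + (g - d) / 2,
             x = bandlimitedNoise(round(d * rate), rate, profile@emgBand[1],
                                  profile@emgBand[2]) *
               trapezoidEnvelope(round(d * rate)) * talkAmp)
      }
    })
    if (!is.null(talk)) {
      idx <- round(talk$at * rate) + seq_along(talk$x)
      keep <- idx <= n
      emg[idx[keep]] <- emg[idx[keep]] + talk$x[keep]
    }
  }
  ## -- wrist stream (on the wrist clock) -----------------------------------
  wt <- synthWiTrace(ev, profile, duration, seed = seeds[5],
                     rate = protocol@wiRate,
                     gestureAt = if (injectSync) .sq$interfAt else NULL)
  session <- new("SessionRecording", subject = profile, emg = emg,
                 emgRate = rate, wi = wt$angles,
                 wiTime = wt$time - profile@anchorOffset,
                 wiRate = protocol@wiRate, events = ev,
                 interferenceTruth = numeric(), duration = duration)
  if (!injectSync) return(session)
  injectInterference(session, at = .sq$interfAt, duration = .sq$interfDur,
                     amplitude = .sq$interfAmp, seed = seeds[6])
}

#' Generate a synthetic cohort
#'
#' One session per subject, each with a distinct profile drawn from the
#' cohort variability model; fully reproducible from the seed.
#'
#' @param nSubjects number of subjects (>= 0).
#' @param protocol an [IngestProtocol-class].
#' @param seed RNG seed.
#' @param signals passed to [generateSession()].
#' @return List of [SessionRecording-class] objects.
#' @export
generateCohort <- function(nSubjects, protocol = IngestProtocol(), seed = 1L,
                           signals = TRUE) {
  if (nSubjects < 0) stop("nSubjects must be >= 0")
  if (nSubjects == 0) return(list())
  seeds <- childSeeds(seed, 2L * nSubjects)
  lapply(seq_len(nSubjects), function(i) {
    prof <- sampleSubjectProfile(sprintf("S%02d", i), seeds[i])
    generateSession(prof, protocol, seed = seeds[nSubjects + i],
                    signals = signals)
  })
}

#' Generate a wrist-angle calibration pass
#'
#' Emulates the free eat-and-drink calibration step performed at the start of
#' each session: alternating drinking and eating bouts with rest in between,
#' generated with step transitions so every sample is unambiguously
#' labelled.
#'
#' @param profile a [SubjectProfile-class].
#' @param seed RNG seed.
#' @param nBouts bouts per activity.
#' @param rate sampling rate, Hz.
#' @return list(time, angles, labels, events); labels is a per-sample factor
#'   with levels drink/eat/rest.
#' @export
generateCalibration <- function(profile, seed = 1L, nBouts = 5L, rate = 1000) {
  onsets <- numeric(0); offsets <- numeric(0); kinds <- character(0)
  t <- 2
  for (i in seq_len(nBouts)) {
    onsets <- c(onsets, t); offsets <- c(offsets, t + 2.5); kinds <- c(kinds, "sip")
    t <- t + 2.5 + 2
    onsets <- c(onsets, t); offsets <- c(offsets, t + 3.5); kinds <- c(kinds, "bite")
    t <- t + 3.5 + 2
  }
  ev <- data.frame(kind = kinds,
                   material = ifelse(kinds == "sip", "water", "A"),
                   amount = ifelse(kinds == "sip", 20, 6),
                   onset = onsets, offset = offsets)
  duration <- t + 2
  wt <- synthWiTrace(ev, profile, duration, seed = seed, rate = rate,
                     rampSec = 0)
  lab <- rep("rest", length(wt$time))
  for (i in seq_len(nrow(ev))) {
    inEv <- wt$time >= ev$onset[i] & wt$time < ev$offset[i]
    lab[inEv] <- if (ev$kind[i] == "sip") "drink" else "eat"
  }
  list(time = wt$time, angles = wt$angles,
       labels = factor(lab, levels = c("drink", "eat", "rest")), events = ev)
}

#' Write / read a session as flat CSV files
#'
#' Layout: `emg.csv` (t, mv), `wi.csv` (t, x, y, z), `events.csv`
#' (kind, material, amount, onset, offset) and `meta.json` (subject profile,
#' rates, duration, interference truth).
#'
#' @param session a [SessionRecording-class].
#' @param dir output directory (created if needed).
#' @return `writeSessionCsv` returns `dir` invisibly; `readSessionCsv`
#'   returns the reconstructed [SessionRecording-class].
#' @export
writeSessionCsv <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(session@emg)
  utils::write.csv(data.frame(t = (seq_len(n) - 1) / session@emgRate,
                              mv = session@emg),
                   file.path(dir, "emg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t = session@wiTime, x = session@wi[, 1],
                              y = session@wi[, 2], z = session@wi[, 3]),
                   file.path(dir, "wi.csv"), row.names = FALSE)
  utils::write.csv(session@events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  p <- session@subject
  meta <- list(subjectId = p@subjectId, emgGain = p@emgGain,
               durGain = p@durGain, noiseSd = p@noiseSd,
               emgBand = p@emgBand, anchorOffset = p@anchorOffset,
               drinkAngles = p@drinkAngles, eatAngles = p@eatAngles,
               restAngles = p@restAngles,
               emgRate = session@emgRate, wiRate = session@wiRate,
               duration = session@duration,
               interferenceTruth = session@interferenceTruth)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeSessionCsv
#' @export
readSessionCsv <- function(dir) {
  emg <- utils::read.csv(file.path(dir, "emg.csv"))
  wi <- utils::read.csv(file.path(dir, "wi.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  toMat <- function(m) matrix(unlist(m), 2, 3,
                              dimnames = list(c("lo", "hi"), NULL))
  prof <- new("SubjectProfile", subjectId = meta$subjectId,
              emgGain = meta$emgGain, durGain = meta$durGain,
              noiseSd = meta$noiseSd,
              emgBand = as.numeric(unlist(meta$emgBand)),
              drinkAngles = toMat(meta$drinkAngles),
              eatAngles = toMat(meta$eatAngles),
              restAngles = toMat(meta$restAngles),
              anchorOffset = meta$anchorOffset)
  new("SessionRecording", subject = prof, emg = emg$mv, emgRate = meta$emgRate,
      wi = as.matrix(wi[, c("x", "y", "z")]), wiTime = wi$t,
      wiRate = meta$wiRate, events = ev,
      interferenceTruth = as.numeric(unlist(meta$interferenceTruth)),
      duration = meta$duration)
}
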