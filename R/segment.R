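## Activity demarcation from wrist angles, mapping onto the sEMG clock, and
## isolation of sip-swallow / bite-chew-swallow burst complexes.

#' Calibrate per-axis wrist-angle thresholds
#'
#' From a labelled calibration pass (per-sample drink/eat/rest labels), learns
#' the per-activity per-axis angle ranges and fits a decision tree on the
#' three axes; the tree is what demarcation uses, the ranges document it.
#'
#' @param angles n x 3 matrix of X/Y/Z angles, degrees.
#' @param labels per-sample factor/character with at least drink and eat
#'   present (a rest class is allowed).
#' @return An [AngleThresholds-class].
#' @export
calibrateThresholds <- function(angles, labels) {
  labels <- factor(labels)
  acts <- intersect(c("drink", "eat"), levels(droplevels(labels)))
  if (length(acts) < 2) stop("calibration data must contain both activities")
  rng <- lapply(c(drink = "drink", eat = "eat"), function(a) {
    m <- apply(angles[labels == a, , drop = FALSE], 2, range)
    rownames(m) <- c("lo", "hi")
    m
  })
  df <- data.frame(activity = droplevels(labels), x = angles[, 1],
                   y = angles[, 2], z = angles[, 3])
  tree <- rpart::rpart(activity ~ x + y + z, data = df, method = "class",
                       control = rpart::rpart.control(minsplit = 10, cp = 0,
                                                      xval = 0))
  new("AngleThresholds", ranges = rng, tree = tree)
}

## Per-sample activity labels from calibrated thresholds.
classifyAngles <- function(angles, thresholds) {
  df <- data.frame(x = angles[, 1], y = angles[, 2], z = angles[, 3])
  if (!is.null(thresholds@tree)) {
    as.character(predict(thresholds@tree, df, type = "class"))
  } else {
    lab <- rep("rest", nrow(df))
    for (a in c("drink", "eat")) {
      r <- thresholds@ranges[[a]]
      inBand <- df$x >= r[1, 1] & df$x <= r[2, 1] &
        df$y >= r[1, 2] & df$y <= r[2, 2]
      lab[inBand] <- a
    }
    lab
  }
}

#' Demarcate eating/drinking periods from the wrist stream
#'
#' Classifies every sample with the calibrated thresholds, takes maximal
#' same-activity runs, closes gaps shorter than `gapSec` and discards runs
#' shorter than `minDuration`.
#'
#' @param wiTime wrist timestamps, seconds.
#' @param angles n x 3 angle matrix, degrees.
#' @param thresholds an [AngleThresholds-class].
#' @param minDuration minimum period length, seconds.
#' @param gapSec maximum gap closed over, seconds.
#' @return data.frame(start, end, activity), times on the wrist clock,
#'   non-overlapping and sorted; zero rows when nothing is found.
#' @export
detectActivityPeriods <- function(wiTime, angles, thresholds,
                                  minDuration = 1, gapSec = 0.5) {
  out <- data.frame(start = numeric(), end = numeric(),
                    activity = character())
  if (!length(wiTime)) return(out)
  lab <- classifyAngles(angles, thresholds)
  rate <- 1 / stats::median(diff(wiTime))
  for (a in c("drink", "eat")) {
    flag <- lab == a
    if (!any(flag)) next
    runs <- closeRunGaps(logicalRuns(flag), gapSec * rate)
    dur <- (runs[, "end"] - runs[, "start"] + 1) / rate
    runs <- runs[dur >= minDuration, , drop = FALSE]
    if (nrow(runs))
      out <- rbind(out, data.frame(
        start = wiTime[runs[, "start"]],
        end = wiTime[runs[, "end"]] + 1 / rate,
        activity = if (a == "drink") "drinking" else "eating"))
  }
  out[order(out$start), , drop = FALSE]
}

#' Map wrist-clock activity periods to sEMG sample intervals
#'
#' Applies the alignment offset and the sEMG rate; intervals are half-open
#' and 0-based, clipped to the signal bounds (with a warning when clipping
#' occurs).
#'
#' @param periods data.frame(start, end, activity) on the wrist clock.
#' @param alignment a [StreamAlignment-class].
#' @param nSamples sEMG signal length, samples.
#' @return data.frame(startSample, endSample, activity).
#' @export
mapToEmg <- function(periods, alignment, nSamples) {
  s <- round((periods$start + alignment@offset) * alignment@emgRate)
  e <- round((periods$end + alignment@offset) * alignment@emgRate)
  if (any(e <= 0 | s >= nSamples))
    stop("a period lies entirely outside the sEMG extent")
  if (any(s < 0 | e > nSamples))
    warning("periods clipped to the sEMG extent")
  data.frame(startSample = pmax(s, 0), endSample = pmin(e, nSamples),
             activity = periods$activity)
}

#' Classify a segment's muscle activity magnitude
#'
#' "high" when the 95th percentile of the segment's rectified-smoothed
#' envelope exceeds `k` times the low-activity reference (the median envelope
#' amplitude of drinking segments from the calibration pass); "low"
#' otherwise.  Deterministic.
#'
#' @param segment sEMG samples.
#' @param referenceLow low-MAM reference amplitude, mV.
#' @param k threshold multiplier.
#' @param rate sampling rate, Hz.
#' @return "high" or "low".
#' @export
classifyMam <- function(segment, referenceLow, k = 2.5, rate = 1000) {
  if (!length(segment)) stop("empty segment")
  env <- emgEnvelope(segment, rate)
  if (stats::quantile(env, 0.95, names = FALSE) > k * referenceLow)
    "high" else "low"
}

## Median rectified-smoothed amplitude over drinking intervals; the low-MAM
## reference used by classifyMam.
drinkingReference <- function(emg, intervals, rate = 1000) {
  idx <- unlist(lapply(which(intervals$activity == "drinking"), function(i)
    (intervals$startSample[i] + 1L):intervals$endSample[i]))
  if (!length(idx)) stop("no drinking intervals to calibrate the reference")
  stats::median(emgEnvelope(emg[idx], rate))
}

#' Split activity intervals into swallow-event segments
#'
#' Within each mapped activity interval (padded by `padSec` on both sides)
#' the rectified 50 ms moving-average envelope is thresholded; runs above
#' threshold are closed over gaps shorter than `gapSec` (merging the chew
#' train with its final swallow) and kept when longer than `minBurstSec`.
#' Each surviving burst complex becomes one [SwallowSegment-class].  The MAM
#' class comes from [classifyMam()]; when the session carries ground truth,
#' labels are inherited from the event whose span contains the burst
#' midpoint.
#'
#' @param emg sEMG trace (interference already excised).
#' @param intervals data.frame(startSample, endSample, activity) from
#'   [mapToEmg()].
#' @param subjectId subject identifier stored in the segments.
#' @param referenceLow low-MAM reference for [classifyMam()].
#' @param rate sampling rate, Hz.
#' @param events optional ground-truth event table (session clock).
#' @param gapSec envelope gap-closing constant, seconds.
#' @param minBurstSec minimum burst-complex duration, seconds.
#' @param padSec interval padding, seconds.
#' @return List of [SwallowSegment-class] objects.
#' @export
splitEvents <- function(emg, intervals, subjectId = "?", referenceLow,
                        rate = 1000, events = NULL, gapSec = 1.0,
                        minBurstSec = 0.3, padSec = 0.3) {
  env <- emgEnvelope(emg, rate)
  ## 10th percentile: robust to sessions where bursts dominate the timeline
  noiseFloor <- stats::quantile(env, 0.10, names = FALSE)
  segs <- list()
  for (i in seq_len(nrow(intervals))) {
    a <- max(intervals$startSample[i] - round(padSec * rate), 0)
    b <- min(intervals$endSample[i] + round(padSec * rate), length(emg))
    e <- env[(a + 1L):b]
    thr <- max(3 * noiseFloor, 0.25 * max(e))
    flag <- e > thr
    if (!any(flag)) next
    runs <- closeRunGaps(logicalRuns(flag), gapSec * rate)  # chew-train dips
    runs <- runs[(runs[, "end"] - runs[, "start"] + 1) / rate >= minBurstSec,
                 , drop = FALSE]
    for (j in seq_len(nrow(runs))) {
      s0 <- a + runs[j, "start"] - 1L
      s1 <- a + runs[j, "end"]
      lab <- NA_character_; amt <- NA_real_
      if (!is.null(events) && nrow(events)) {
        mid <- (s0 + s1) / 2 / rate
        hit <- which(events$onset <= mid & events$offset >= mid)
        if (length(hit)) {
          lab <- events$material[hit[1]]
          amt <- events$amount[hit[1]]
        }
      }
      segs[[length(segs) + 1L]] <- new(
        "SwallowSegment", samples = emg[(s0 + 1L):s1], rate = rate,
        mamClass = classifyMam(emg[(s0 + 1L):s1], referenceLow, rate = rate),
        subjectId = subjectId, label = lab, amount = amt,
        startSample = s0, endSample = s1)
    }
  }
  segs
}

#' Run the full segmentation pipeline on one session
#'
#' Synchronizes the streams (interference detection, excision, alignment),
#' demarcates activity periods from the wrist angles, maps them onto the
#' sEMG clock, self-calibrates the low-MAM reference from the drinking
#' periods, and splits the intervals into swallow segments.
#'
#' @param session a [SessionRecording-class] with signals.
#' @param thresholds an [AngleThresholds-class]; when NULL, calibrated from a
#'   generated calibration pass for the session's subject.
#' @param minDuration passed to [detectActivityPeriods()].
#' @param ... passed to [splitEvents()].
#' @return list(segments, alignment, periods, intervals, referenceLow).
#' @export
segmentSession <- function(session, thresholds = NULL, minDuration = 0.6, ...) {
  if (is.null(thresholds)) {
    cal <- generateCalibration(session@subject, seed = 1L)
    thresholds <- calibrateThresholds(cal$angles, cal$labels)
  }
  sy <- syncSession(session)
  periods <- detectActivityPeriods(sy$session@wiTime, sy$session@wi,
                                   thresholds, minDuration = minDuration)
  intervals <- mapToEmg(periods, sy$alignment, length(sy$session@emg))
  refLow <- drinkingReference(sy$session@emg, intervals, session@emgRate)
  segs <- splitEvents(sy$session@emg, intervals,
                      subjectId = session@subject@subjectId,
                      referenceLow = refLow, rate = session@emgRate,
                      events = session@events, ...)
  list(segments = segs, alignment = sy$alignment, periods = periods,
       intervals = intervals, referenceLow = refLow)
}

#' Cut segments directly from ground-truth events
#'
#' Bypasses detection: slices the session's sEMG at the true event spans and
#' attaches the true labels, with the MAM class taken from the event kind.
#' Used to build labelled feature tables at cohort scale.
#'
#' @param session a [SessionRecording-class] with signals.
#' @return List of [SwallowSegment-class] objects.
#' @export
segmentsFromTruth <- function(session) {
  rate <- session@emgRate
  ev <- session@events
  lapply(seq_len(nrow(ev)), function(i) {
    s0 <- round(ev$onset[i] * rate)
    s1 <- min(round(ev$offset[i] * rate), length(session@emg))
    new("SwallowSegment", samples = session@emg[(s0 + 1L):s1], rate = rate,
        mamClass = if (ev$kind[i] == "sip") "low" else "high",
        subjectId = session@subject@subjectId,
        label = ev$material[i], amount = ev$amount[i],
        startSample = s0, endSample = s1)
  })
}
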