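## S4 containers for the ingestion-monitoring pipeline.

#' Study protocol for a synthetic recording session
#'
#' Describes the per-subject ingestion protocol: how many water sips of each
#' volume and how many solid boluses of each (material, weight) cell a session
#' contains, plus the sampling rates of the two streams and the nominal
#' session duration.
#'
#' @slot nSipsPerVolume sips per water volume level.
#' @slot sipVolumes water sip volumes in ml.
#' @slot nBolusesPerCell boluses per (material, weight) cell.
#' @slot materials solid material codes, ordered hard to soft
#'   (A = carrot, B = cheese, C = banana).
#' @slot weights solid bolus weights in grams.
#' @slot emgRate,wiRate sampling rates in Hz of the sEMG and wrist-angle
#'   streams.
#' @slot durationSec nominal session duration in seconds.
#' @exportClass IngestProtocol
setClass("IngestProtocol", representation(
  nSipsPerVolume = "integer",
  sipVolumes = "numeric",
  nBolusesPerCell = "integer",
  materials = "character",
  weights = "numeric",
  emgRate = "numeric",
  wiRate = "numeric",
  durationSec = "numeric"
))

setValidity("IngestProtocol", function(object) {
  msg <- character()
  if (object@emgRate <= 0 || object@wiRate <= 0)
    msg <- c(msg, "sampling rates must be positive")
  if (object@nSipsPerVolume < 0L || object@nBolusesPerCell < 0L)
    msg <- c(msg, "event counts must be non-negative")
  if (any(object@sipVolumes <= 0) || any(object@weights <= 0))
    msg <- c(msg, "sip volumes and bolus weights must be positive")
  if (object@durationSec <= 0) msg <- c(msg, "durationSec must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a study protocol
#'
#' Defaults follow the study design: 10 sips at each of 10/20/30/40 ml
#' (40 sips, one liter per participant) and 5 boluses in each of the
#' 9 material-by-weight cells (45 boluses), both streams at 1 kHz.  The
#' nominal duration is compressed to 10 minutes (configurable up to the
#' one-hour session it emulates); event counts are unaffected.
#'
#' @param nSipsPerVolume,sipVolumes,nBolusesPerCell,materials,weights,emgRate,wiRate,durationSec
#'   see the class slots.
#' @return An [IngestProtocol-class] object.
#' @export
IngestProtocol <- function(nSipsPerVolume = 10L,
                           sipVolumes = c(10, 20, 30, 40),
                           nBolusesPerCell = 5L,
                           materials = c("A", "B", "C"),
                           weights = c(3, 6, 9),
                           emgRate = 1000,
                           wiRate = 1000,
                           durationSec = 600) {
  new("IngestProtocol",
      nSipsPerVolume = as.integer(nSipsPerVolume),
      sipVolumes = sipVolumes,
      nBolusesPerCell = as.integer(nBolusesPerCell),
      materials = materials, weights = weights,
      emgRate = emgRate, wiRate = wiRate, durationSec = durationSec)
}

setMethod("show", "IngestProtocol", function(object) {
  cat("IngestProtocol:",
      object@nSipsPerVolume * length(object@sipVolumes), "sips (",
      paste(object@sipVolumes, collapse = "/"), "ml ),",
      object@nBolusesPerCell * length(object@materials) * length(object@weights),
      "boluses (", paste(object@materials, collapse = "/"), "x",
      paste(object@weights, collapse = "/"), "g ) @",
      object@emgRate, "Hz\n")
})

#' Per-subject generative profile
#'
#' Captures the inter-subject variability the generator emulates: a
#' multiplicative sEMG gain, a duration (pace) gain, baseline noise level,
#' per-activity wrist-angle bands, and the start-time offset between the two
#' sensor clocks.
#'
#' @slot subjectId subject identifier.
#' @slot emgGain dimensionless multiplicative sEMG amplitude factor (> 0).
#' @slot durGain dimensionless event-duration factor (> 0).
#' @slot noiseSd baseline sEMG noise standard deviation, mV.
#' @slot emgBand length-2 numeric, the subject's sEMG burst carrier band in
#'   Hz (a subject-specific spectral signature).
#' @slot drinkAngles,eatAngles,restAngles 2 x 3 matrices of per-axis
#'   (X, Y, Z) inclusive degree ranges, rows = (lo, hi), all within [0, 360).
#' @slot anchorOffset seconds to add to wrist-stream timestamps to express
#'   them on the sEMG clock (the generator's ground-truth alignment).
#' @exportClass SubjectProfile
setClass("SubjectProfile", representation(
  subjectId = "character",
  emgGain = "numeric",
  durGain = "numeric",
  noiseSd = "numeric",
  emgBand = "numeric",
  drinkAngles = "matrix",
  eatAngles = "matrix",
  restAngles = "matrix",
  anchorOffset = "numeric"
))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (object@emgGain <= 0) msg <- c(msg, "emgGain must be > 0")
  if (object@durGain <= 0) msg <- c(msg, "durGain must be > 0")
  if (length(object@emgBand) != 2 || object@emgBand[1] >= object@emgBand[2])
    msg <- c(msg, "emgBand must be an increasing length-2 range")
  for (nm in c("drinkAngles", "eatAngles", "restAngles")) {
    a <- slot(object, nm)
    if (!all(dim(a) == c(2, 3))) msg <- c(msg, paste(nm, "must be 2 x 3"))
    else if (any(a < 0) || any(a >= 360))
      msg <- c(msg, paste(nm, "ranges must lie within [0, 360)"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf("SubjectProfile %s: emgGain %.3f, durGain %.3f, noiseSd %.4f mV, anchorOffset %+.2f s\n",
              object@subjectId, object@emgGain, object@durGain,
              object@noiseSd, object@anchorOffset))
})

#' One subject's recording session
#'
#' Holds the two sensor streams on their native clocks plus the ground-truth
#' event table.  Events are stored on the sEMG (session) clock; wrist-stream
#' timestamps are offset by the subject's `anchorOffset` until the streams are
#' aligned.
#'
#' @slot subject the [SubjectProfile-class].
#' @slot emg single-channel sEMG trace, mV (may be empty when the session was
#'   generated event-schedule-only).
#' @slot emgRate sEMG sampling rate, Hz.
#' @slot wi n x 3 matrix of X/Y/Z wrist tilt angles, degrees.
#' @slot wiTime wrist-stream timestamps on the wrist-sensor clock, seconds.
#' @slot wiRate wrist-stream sampling rate, Hz.
#' @slot events data.frame(kind, material, amount, onset, offset): ground
#'   truth; `kind` is "sip" or "bite", times in seconds on the session clock.
#' @slot interferenceTruth length-2 integer vector, the half-open 0-based
#'   sEMG sample interval of the injected synchronization interference
#'   (length 0 if none).
#' @slot duration session duration, seconds.
#' @exportClass SessionRecording
setClass("SessionRecording", representation(
  subject = "SubjectProfile",
  emg = "numeric",
  emgRate = "numeric",
  wi = "matrix",
  wiTime = "numeric",
  wiRate = "numeric",
  events = "data.frame",
  interferenceTruth = "numeric",
  duration = "numeric"
))

setValidity("SessionRecording", function(object) {
  msg <- character()
  ev <- object@events
  need <- c("kind", "material", "amount", "onset", "offset")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, "events must have columns kind, material, amount, onset, offset")
  } else if (nrow(ev)) {
    if (any(ev$offset <= ev$onset)) msg <- c(msg, "event offset must exceed onset")
    if (is.unsorted(ev$onset)) msg <- c(msg, "events must be sorted by onset")
    if (any(utils::head(ev$offset, -1) > utils::tail(ev$onset, -1)))
      msg <- c(msg, "events must not overlap")
    if (any((ev$kind == "sip") != (ev$material == "water")))
      msg <- c(msg, "kind 'sip' must pair with material 'water'")
  }
  if (nrow(object@wi) && ncol(object@wi) != 3)
    msg <- c(msg, "wi must have 3 columns (X, Y, Z)")
  if (nrow(object@wi) != length(object@wiTime))
    msg <- c(msg, "wi and wiTime lengths differ")
  if (length(object@interferenceTruth) %in% c(0L, 2L) == FALSE)
    msg <- c(msg, "interferenceTruth must be empty or length 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SessionRecording", function(object) {
  cat(sprintf("SessionRecording %s: %.0f s, %d sEMG samples @ %g Hz, %d WI samples, %d events (%d sips, %d bites)%s\n",
              object@subject@subjectId, object@duration, length(object@emg),
              object@emgRate, nrow(object@wi), nrow(object@events),
              sum(object@events$kind == "sip"),
              sum(object@events$kind == "bite"),
              if (length(object@interferenceTruth)) ", interference injected" else ""))
})

#' Detected abrupt-change window in a sampled signal
#'
#' Half-open 0-based sample interval with the detector's peak score (the
#' high-frequency energy ratio at its maximum).
#'
#' @slot startSample,endSample half-open 0-based sample indices.
#' @slot score peak detector statistic (dimensionless).
#' @exportClass ChangeWindow
setClass("ChangeWindow", representation(
  startSample = "numeric", endSample = "numeric", score = "numeric"
))

setValidity("ChangeWindow", function(object) {
  if (object@startSample < 0 || object@endSample <= object@startSample)
    "require 0 <= startSample < endSample" else TRUE
})

setMethod("show", "ChangeWindow", function(object) {
  cat(sprintf("ChangeWindow: samples [%d, %d), score %.3f\n",
              as.integer(object@startSample), as.integer(object@endSample),
              object@score))
})

#' Temporal alignment between the wrist and sEMG streams
#'
#' @slot offset seconds to add to wrist-stream timestamps to express them on
#'   the sEMG clock.
#' @slot emgRate sEMG sampling rate, Hz.
#' @exportClass StreamAlignment
setClass("StreamAlignment", representation(
  offset = "numeric", emgRate = "numeric"
))

setValidity("StreamAlignment", function(object) {
  if (!is.finite(object@offset)) "offset must be finite" else TRUE
})

setMethod("show", "StreamAlignment", function(object) {
  cat(sprintf("StreamAlignment: offset %+.4f s @ %g Hz\n",
              object@offset, object@emgRate))
})

#' Calibrated wrist-angle thresholds
#'
#' Per-activity, per-axis inclusive degree ranges learned from a calibration
#' pass, plus the decision tree fitted on the same samples.  Drinking and
#' eating ranges must be disjoint on at least one axis.
#'
#' @slot ranges named list (drink, eat) of 2 x 3 matrices, rows (lo, hi),
#'   columns (X, Y, Z).
#' @slot tree the fitted rpart classification tree (or NULL).
#' @exportClass AngleThresholds
setClass("AngleThresholds", representation(
  ranges = "list", tree = "ANY"
))

setValidity("AngleThresholds", function(object) {
  if (!all(c("drink", "eat") %in% names(object@ranges)))
    return("ranges must contain 'drink' and 'eat'")
  d <- object@ranges$drink; e <- object@ranges$eat
  disjoint <- vapply(1:3, function(j) d[2, j] < e[1, j] || e[2, j] < d[1, j],
                     logical(1))
  if (!any(disjoint)) "drink and eat ranges must be disjoint on >= 1 axis"
  else TRUE
})

setMethod("show", "AngleThresholds", function(object) {
  cat("AngleThresholds:\n")
  for (nm in names(object@ranges)) {
    r <- object@ranges[[nm]]
    cat(sprintf("  %-5s X [%.0f, %.0f]  Y [%.0f, %.0f]  Z [%.0f, %.0f]\n",
                nm, r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
})

#' One segmented swallow event
#'
#' An sEMG burst complex (sip-swallow or bite-chew-swallow) cut from a
#' session, with its muscle-activity-magnitude class and, when ground truth
#' was available, its material/amount labels.
#'
#' @slot samples sEMG samples, mV.
#' @slot rate sampling rate, Hz.
#' @slot mamClass "high" or "low".
#' @slot subjectId subject identifier.
#' @slot label material label: "water", "A", "B", "C" or NA.
#' @slot amount sip volume (ml) or bolus weight (g), NA when unknown.
#' @slot startSample,endSample half-open 0-based interval in the session
#'   sEMG trace.
#' @exportClass SwallowSegment
setClass("SwallowSegment", representation(
  samples = "numeric", rate = "numeric", mamClass = "character",
  subjectId = "character", label = "character", amount = "numeric",
  startSample = "numeric", endSample = "numeric"
))

setValidity("SwallowSegment", function(object) {
  msg <- character()
  if (!object@mamClass %in% c("high", "low"))
    msg <- c(msg, "mamClass must be 'high' or 'low'")
  if (object@endSample <= object@startSample)
    msg <- c(msg, "endSample must exceed startSample")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SwallowSegment", function(object) {
  cat(sprintf("SwallowSegment %s: %d samples, MAM %s, label %s (%.0f), samples [%d, %d)\n",
              object@subjectId, length(object@samples), object@mamClass,
              object@label, object@amount,
              as.integer(object@startSample), as.integer(object@endSample)))
})

#' Fivefold cross-validation plan
#'
#' @slot scheme "AS" (among-subject: every subject contributes to train and
#'   test of every fold) or "CS" (cross-subject: subject-disjoint folds).
#' @slot k number of folds.
#' @slot folds list of `list(train, test)` integer index vectors; the test
#'   sets partition the sample set.
#' @slot seed RNG seed the plan was drawn with.
#' @exportClass FoldPlan
setClass("FoldPlan", representation(
  scheme = "character", k = "integer", folds = "list", seed = "integer"
))

setValidity("FoldPlan", function(object) {
  if (!object@scheme %in% c("AS", "CS")) return("scheme must be 'AS' or 'CS'")
  tests <- lapply(object@folds, `[[`, "test")
  all_idx <- sort(unlist(tests))
  if (anyDuplicated(all_idx)) return("test folds must be pairwise disjoint")
  TRUE
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %s, k = %d, %d samples, seed %d\n", object@scheme,
              object@k, length(unlist(lapply(object@folds, `[[`, "test"))),
              object@seed))
})

#' Evaluation report
#'
#' Per (task, model, scheme) metrics with fold-level values and means.
#'
#' @slot results data.frame with columns task, model, scheme, fold
#'   (0 = mean over folds) and metric columns.
#' @slot config the experiment configuration (list).
#' @exportClass EvaluationReport
setClass("EvaluationReport", representation(
  results = "data.frame", config = "list"
))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", nrow(object@results), "rows\n")
  print(utils::head(object@results[object@results$fold == 0, ], 20))
})
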