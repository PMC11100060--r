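## Stream synchronization: locate the induced broadband interference window
## in the sEMG, excise it, and align the wrist stream to the sEMG clock using
## the simultaneous wrist-flick transient as the wrist-side anchor.

#' Detect the synchronization interference window in an sEMG trace
#'
#' Sliding-window change detector: for each window the high-frequency energy
#' ratio (energy above `hfCutoff` divided by total energy) is computed; a
#' window is a candidate when its ratio exceeds an adaptive threshold
#' (median + 5 x MAD of the ratio trace) *and* its high-frequency energy
#' exceeds three times the trace median (the energy gate rejects ratio
#' fluctuations of the quiet baseline, whose absolute energy is tiny).  The
#' maximal run of at least `minRun` consecutive candidate windows is kept and
#' its onset/offset are refined to sample precision on the high-passed
#' envelope.  The detector is deliberately pluggable (see [splitEvents()]):
#' any routine honouring the same contract - localize a sudden broadband
#' window - can be swapped in.
#'
#' @param emg sEMG samples (mV).
#' @param rate sampling rate, Hz.
#' @param windowLen sliding-window length, samples.
#' @param hfCutoff high-frequency cutoff, Hz.
#' @param penalty threshold multiplier on the MAD (the adaptive penalty).
#' @param minRun minimum run of candidate windows.
#' @return A [ChangeWindow-class], or NULL when no window exceeds the
#'   threshold ("no interference found").
#' @export
detectInterferenceWindow <- function(emg, rate = 1000, windowLen = 200,
                                     hfCutoff = 200, penalty = 5,
                                     minRun = 2L) {
  n <- length(emg)
  if (n <= 2 * windowLen) stop("signal shorter than 2 x windowLen")
  hp <- highpass(emg, rate, hfCutoff)
  hop <- max(1L, windowLen %/% 4L)
  starts <- seq(1L, n - windowLen + 1L, by = hop)
  csT <- cumsum(c(0, emg^2))
  csH <- cumsum(c(0, hp^2))
  eT <- csT[starts + windowLen] - csT[starts]
  eH <- csH[starts + windowLen] - csH[starts]
  ratio <- eH / pmax(eT, .Machine$double.eps)
  ## the ratio is bounded by 1 and broadband interference carries most of its
  ## energy above the cutoff, while even the widest burst carriers stay well
  ## below; the adaptive threshold is clamped so a broadly spread trace
  ## (sessions dominated by bursts) cannot push median + penalty * MAD past
  ## the interference's own ratio
  thr <- min(stats::median(ratio) + penalty * stats::mad(ratio), 0.8)
  cand <- ratio > thr & eH > 3 * stats::quantile(eH, 0.25, names = FALSE)
  if (!any(cand)) return(NULL)
  runs <- logicalRuns(cand)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= minRun, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  peak <- vapply(seq_len(nrow(runs)), function(i)
    max(ratio[runs[i, "start"]:runs[i, "end"]]), numeric(1))
  r <- runs[which.max(peak), ]
  coarse0 <- starts[r["start"]]
  coarse1 <- min(starts[r["end"]] + windowLen - 1L, n)
  ## refine boundaries on the high-passed envelope, locally
  lo <- max(1L, coarse0 - windowLen)
  hi <- min(n, coarse1 + windowLen)
  env <- emgEnvelope(hp[lo:hi], rate, smoothMs = 20)
  ## robust refinement level: a quarter of the upper-quartile envelope (the
  ## typical in-window level, immune to heavy-tailed spikes); brief dips are
  ## closed over before keeping the run that contains the envelope peak
  eThr <- 0.25 * stats::quantile(env, 0.75, names = FALSE)
  eruns <- closeRunGaps(logicalRuns(env > eThr), round(0.05 * rate))
  am <- which.max(env)
  hit <- which(eruns[, "start"] <= am & eruns[, "end"] >= am)[1]
  if (is.na(hit)) hit <- which.max(eruns[, "end"] - eruns[, "start"])
  s0 <- lo + eruns[hit, "start"] - 1L
  s1 <- lo + eruns[hit, "end"] - 1L
  new("ChangeWindow", startSample = s0 - 1L, endSample = s1,
      score = max(peak))
}

#' Excise a detected window by linear interpolation
#'
#' Samples inside the (half-open, 0-based) window are replaced by the
#' straight line between the boundary samples; the series length is
#' preserved so downstream sample indices remain valid.
#'
#' @param emg sEMG samples.
#' @param window a [ChangeWindow-class].
#' @return The bridged sEMG trace, same length.
#' @export
exciseWindow <- function(emg, window) {
  n <- length(emg)
  i0 <- as.integer(window@startSample)
  i1 <- as.integer(window@endSample)
  if (i0 < 0 || i1 > n) stop("window outside the signal")
  a <- if (i0 >= 1) emg[i0] else emg[i1 + 1L]
  b <- if (i1 < n) emg[i1 + 1L] else emg[i0]
  if (i0 == 0 && i1 == n) { a <- emg[1]; b <- emg[n] }
  emg[(i0 + 1L):i1] <- seq(a, b, length.out = i1 - i0 + 2L)[-c(1L, i1 - i0 + 2L)]
  emg
}

#' Locate the wrist-side synchronization anchor
#'
#' The synchronization gesture (moving the wrist sensor against the sEMG
#' electrode) produces a sharp angle transient; its instant is taken as the
#' first time, within the first `searchSec` seconds of the wrist stream, at
#' which the smoothed angular-velocity magnitude reaches half of its local
#' maximum.
#'
#' @param wiTime wrist timestamps, seconds (wrist clock).
#' @param wi n x 3 angle matrix, degrees.
#' @param searchSec search horizon from the stream start, seconds.
#' @param rate sampling rate, Hz.
#' @return Anchor time in seconds on the wrist clock.
#' @export
wiAnchorTime <- function(wiTime, wi, searchSec = 60, rate = 1000) {
  keep <- wiTime <= wiTime[1] + searchSec
  v <- rowSums(abs(apply(wi[keep, , drop = FALSE], 2, function(a) c(0, diff(a)))))
  v <- movingAverage(v * rate, round(0.02 * rate))
  if (max(v) <= 0) stop("no anchor transient found in the wrist stream")
  iPk <- which.max(v)
  iOn <- which(v[seq_len(iPk)] >= max(v) / 2)[1]
  wiTime[iOn]
}

#' Align the wrist stream to the sEMG clock
#'
#' The sEMG-side anchor (the interference-window onset) is mapped exactly to
#' the wrist-side anchor; both devices share the nominal rate, so the mapping
#' is linear elsewhere with no drift model.
#'
#' @param emgAnchor a [ChangeWindow-class] from [detectInterferenceWindow()].
#' @param wiAnchor wrist-side anchor time, seconds (wrist clock), from
#'   [wiAnchorTime()].
#' @param emgRate sEMG sampling rate, Hz.
#' @return A [StreamAlignment-class]; its offset, added to wrist timestamps,
#'   expresses them on the sEMG clock.
#' @export
alignStreams <- function(emgAnchor, wiAnchor, emgRate = 1000) {
  if (is.null(emgAnchor)) stop("missing sEMG anchor")
  if (!is.finite(wiAnchor)) stop("missing wrist anchor")
  new("StreamAlignment", offset = emgAnchor@startSample / emgRate - wiAnchor,
      emgRate = emgRate)
}

#' Synchronize a session end to end
#'
#' Detects the interference window, excises it from the sEMG, finds the
#' wrist anchor and returns the aligned session plus the alignment.
#'
#' @param session a [SessionRecording-class].
#' @param ... passed to [detectInterferenceWindow()].
#' @return list(session, alignment, window): the session with the
#'   interference bridged, the [StreamAlignment-class] and the detected
#'   [ChangeWindow-class].
#' @export
syncSession <- function(session, ...) {
  w <- detectInterferenceWindow(session@emg, rate = session@emgRate, ...)
  if (is.null(w)) stop("no interference found; cannot synchronize")
  session@emg <- exciseWindow(session@emg, w)
  anchor <- wiAnchorTime(session@wiTime, session@wi, rate = session@wiRate)
  list(session = session,
       alignment = alignStreams(w, anchor, session@emgRate),
       window = w)
}
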