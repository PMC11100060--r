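## The forty time-frequency sEMG features.
##
## The registry pins one canonical formula per feature name, following the
## standard EMG-feature compendia.  Ambiguous printed items are resolved as
## documented in featureRegistry() and the methods vignette; alternates can
## be swapped by replacing registry entries.  Log-of-nonpositive quantities
## return the finite, orderable sentinel -30.

.logSentinel <- -30

safeLog <- function(v, base = exp(1)) {
  if (!is.finite(v) || v <= 0) .logSentinel else log(v, base = base)
}

#' Feature configuration
#'
#' Free parameters of the feature registry.  The study reports none, so all
#' are exposed here: detection thresholds in mV, the autoregressive model
#' order (each order contributes one coefficient to the vector; the default 2
#' keeps the vector at exactly 40 entries), the V-order exponent and the
#' temporal-moment order.
#'
#' @param zcThreshold,sscThreshold,wampThreshold,myopThreshold thresholds, mV.
#' @param arOrder autoregressive model order (>= 1).
#' @param vOrder V-order exponent.
#' @param tmOrder temporal moment order.
#' @return A list of class "FeatureConfig".
#' @export
featureConfig <- function(zcThreshold = 0, sscThreshold = 0,
                          wampThreshold = 0.005, myopThreshold = 0.005,
                          arOrder = 2L, vOrder = 2, tmOrder = 3L) {
  stopifnot(zcThreshold >= 0, sscThreshold >= 0, wampThreshold >= 0,
            myopThreshold >= 0, arOrder >= 1, vOrder >= 1, tmOrder >= 1)
  structure(list(zcThreshold = zcThreshold, sscThreshold = sscThreshold,
                 wampThreshold = wampThreshold, myopThreshold = myopThreshold,
                 arOrder = as.integer(arOrder), vOrder = vOrder,
                 tmOrder = as.integer(tmOrder)),
            class = "FeatureConfig")
}

#' Canonical feature names
#'
#' The 38 fixed registry names plus AR1..AR<arOrder>, in registry order;
#' exactly 40 names under the default configuration.
#'
#' @param config a [featureConfig()].
#' @return Character vector of feature names.
#' @export
featureNames <- function(config = featureConfig()) {
  c("EMAV", "EWL", "NZC", "ASE", "ASS", "MSR", "LTKEO", "LCOV", "LDASDV",
    "DAMV", "DVARV", "VORDER", "TM", "DABS",
    paste0("AR", seq_len(config$arOrder)),
    "MAD", "IQR", "VAREMG", "WAMP", "MFL", "SKEW", "KURT", "COV", "SD",
    "VAR", "AE", "IEMG", "MAV", "SSC", "ZC", "WL", "RMS", "AAC", "DASDV",
    "LOG", "MMAV", "MMAV2", "MYOP", "SSI")
}

#' Count threshold-crossing sign changes
#'
#' Number of i with a strict sign change between consecutive samples
#' (x[i] * x[i+1] < 0) whose step |x[i] - x[i+1]| is at least `threshold`.
#'
#' @param x samples.
#' @param threshold amplitude threshold, mV.
#' @return Integer count.
#' @export
zeroCrossings <- function(x, threshold = 0) {
  if (length(x) < 2) stop("need at least 2 samples")
  a <- x[-length(x)]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= threshold)
}

#' Willison amplitude
#'
#' Count of consecutive-sample steps strictly exceeding `threshold`.
#'
#' @inheritParams zeroCrossings
#' @return Integer count.
#' @export
willisonAmplitude <- function(x, threshold) {
  if (length(x) < 2) stop("need at least 2 samples")
  sum(abs(diff(x)) > threshold)
}

#' Maximum fractal length
#'
#' log10 of the square root of the summed squared first differences; the
#' sentinel -30 for a constant segment.
#'
#' @param x samples.
#' @return Numeric value.
#' @export
maximumFractalLength <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  safeLog(sqrt(sum(diff(x)^2)), base = 10)
}

## Slope sign changes: strict product-of-successive-slopes threshold, so a
## constant segment counts zero at threshold 0.
slopeSignChanges <- function(x, threshold = 0) {
  if (length(x) < 3) return(0L)
  m <- x[2:(length(x) - 1)]
  sum((m - x[1:(length(x) - 2)]) * (m - x[3:length(x)]) > threshold)
}

## Piecewise EMAV/EWL exponent: 0.75 in the central 20-80 % span, 0.5 in the
## tails.
.emavExponent <- function(n) {
  i <- seq_len(n)
  ifelse(i >= 0.2 * n & i <= 0.8 * n, 0.75, 0.5)
}

## MMAV / MMAV2 weights over the central 25-75 % span.
.mmavWeights <- function(n, version = 1L) {
  i <- seq_len(n)
  w <- rep(1, n)
  lo <- i < 0.25 * n
  hi <- i > 0.75 * n
  if (version == 1L) {
    w[lo | hi] <- 0.5
  } else {
    w[lo] <- 4 * i[lo] / n
    w[hi] <- 4 * (n - i[hi]) / n
  }
  w
}

## Yule-Walker autoregressive coefficients (order p), matching stats::ar.yw.
arCoefficients <- function(x, p) {
  if (stats::var(x) == 0) return(rep(0, p))  # degenerate series
  fit <- stats::ar(x, aic = FALSE, order.max = p, method = "yule-walker",
                   demean = TRUE)
  co <- rep(0, p)
  co[seq_along(fit$ar)] <- fit$ar
  co
}

#' Extract the forty-feature vector of one segment
#'
#' Computes every registry feature from the segment as a whole (no
#' windowing).  Deterministic; log-based features of degenerate segments
#' return the sentinel -30.
#'
#' @param x sEMG samples (length >= arOrder + 2).
#' @param config a [featureConfig()].
#' @return Named numeric vector, `featureNames(config)` order.
#' @export
extractFeatures <- function(x, config = featureConfig()) {
  n <- length(x)
  if (n < config$arOrder + 2) stop("segment too short")
  d <- diff(x)
  ax <- abs(x)
  mu <- mean(x)
  pE <- .emavExponent(n)
  m2 <- mean((x - mu)^2)
  sdev <- stats::sd(x)
  dasdv <- sqrt(sum(d^2) / (n - 1))
  v <- config$vOrder
  out <- c(
    EMAV = mean(ax^pE),
    EWL = sum(abs(d)^pE[-1]),
    NZC = zeroCrossings(x - mu, config$zcThreshold),
    ASE = abs(sum(sign(x) * ax^pE)),
    ASS = abs(sum(sign(x) * sqrt(ax))),
    MSR = mean(sqrt(ax)),
    LTKEO = safeLog(sum(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])),
    LCOV = if (sdev == 0) .logSentinel else safeLog(sdev / abs(mu)),
    LDASDV = safeLog(dasdv),
    DAMV = mean(abs(d)),
    DVARV = sum(d^2) / (n - 2),
    VORDER = mean(ax^v)^(1 / v),
    TM = abs(mean(x^config$tmOrder)),
    DABS = abs(sum(d)),
    setNames(arCoefficients(x, config$arOrder),
             paste0("AR", seq_len(config$arOrder))),
    MAD = mean(abs(x - mu)),
    IQR = stats::quantile(x, 0.75, names = FALSE) -
      stats::quantile(x, 0.25, names = FALSE),
    VAREMG = sum(x^2) / (n - 1),
    WAMP = willisonAmplitude(x, config$wampThreshold),
    MFL = maximumFractalLength(x),
    SKEW = if (m2 == 0) 0 else mean((x - mu)^3) / m2^1.5,
    KURT = if (m2 == 0) 0 else mean((x - mu)^4) / m2^2,
    COV = if (sdev == 0) 0 else sdev / abs(mu),
    SD = sdev,
    VAR = stats::var(x),
    AE = mean(x^2),
    IEMG = sum(ax),
    MAV = mean(ax),
    SSC = slopeSignChanges(x, config$sscThreshold),
    ZC = zeroCrossings(x, config$zcThreshold),
    WL = sum(abs(d)),
    RMS = sqrt(mean(x^2)),
    AAC = sum(abs(d)) / (n - 1),
    DASDV = dasdv,
    LOG = exp(mean(log(pmax(ax, .Machine$double.xmin)))) *
      (if (any(ax == 0)) 0 else 1),
    MMAV = mean(.mmavWeights(n, 1L) * ax),
    MMAV2 = mean(.mmavWeights(n, 2L) * ax),
    MYOP = mean(ax >= config$myopThreshold),
    SSI = sum(x^2)
  )
  out[featureNames(config)]
}

#' Feature registry
#'
#' Machine-readable ledger mapping each canonical feature name to its pinned
#' formula and free parameters.  Printed-source ambiguities resolved here:
#' the duplicated absolute-mean-difference rows become DAMV (mean |diff|)
#' and DABS (|sum of diffs|); the split "Difference Absolute Standard
#' Deviation" / "Value" rows are the single DASDV; "Log Coefficient of
#' Variation Cardinality" is read as log(COV); the autoregressive model
#' contributes one coefficient per order.
#'
#' @param config a [featureConfig()].
#' @return data.frame(name, formula, parameter).
#' @export
featureRegistry <- function(config = featureConfig()) {
  p <- config
  reg <- rbind(
    c("EMAV", "mean(|x_i|^p_i), p_i = 0.75 center (20-80%), 0.5 tails", ""),
    c("EWL", "sum(|x_i - x_{i-1}|^p_i), same exponent rule", ""),
    c("NZC", "threshold sign changes of the mean-removed signal",
      paste0("zcThreshold=", p$zcThreshold)),
    c("ASE", "|sum(sign(x_i) |x_i|^p_i)|, EMAV exponent rule", ""),
    c("ASS", "|sum(sign(x_i) sqrt|x_i|)|", ""),
    c("MSR", "mean(sqrt|x_i|)", ""),
    c("LTKEO", "log sum(x_i^2 - x_{i-1} x_{i+1})", "sentinel=-30"),
    c("LCOV", "log(SD / |mean|)", "sentinel=-30"),
    c("LDASDV", "log(DASDV)", "sentinel=-30"),
    c("DAMV", "mean|x_{i+1} - x_i|", ""),
    c("DVARV", "sum(diff^2) / (N - 2)", ""),
    c("VORDER", "(mean|x|^v)^(1/v)", paste0("v=", p$vOrder)),
    c("TM", "|mean(x^k)|", paste0("k=", p$tmOrder)),
    c("DABS", "|sum(x_{i+1} - x_i)|", ""),
    cbind(paste0("AR", seq_len(p$arOrder)),
          "Yule-Walker autoregressive coefficient", paste0("order=", p$arOrder)),
    c("MAD", "mean|x - mean(x)|", ""),
    c("IQR", "Q3 - Q1 (type-7 quantiles)", ""),
    c("VAREMG", "sum(x^2) / (N - 1)", ""),
    c("WAMP", "count(|diff| > thr)", paste0("wampThreshold=", p$wampThreshold)),
    c("MFL", "log10 sqrt(sum(diff^2))", "sentinel=-30"),
    c("SKEW", "m3 / m2^1.5", ""),
    c("KURT", "m4 / m2^2", ""),
    c("COV", "SD / |mean|", ""),
    c("SD", "sample standard deviation", ""),
    c("VAR", "sample variance", ""),
    c("AE", "mean(x^2)", ""),
    c("IEMG", "sum|x|", ""),
    c("MAV", "mean|x|", ""),
    c("SSC", "count((x_i-x_{i-1})(x_i-x_{i+1}) > thr)",
      paste0("sscThreshold=", p$sscThreshold)),
    c("ZC", "count(sign change & |step| >= thr)",
      paste0("zcThreshold=", p$zcThreshold)),
    c("WL", "sum|diff|", ""),
    c("RMS", "sqrt(mean(x^2))", ""),
    c("AAC", "sum|diff| / (N - 1)", ""),
    c("DASDV", "sqrt(sum(diff^2) / (N - 1))", ""),
    c("LOG", "exp(mean log|x|)  (0 when any |x| = 0)", ""),
    c("MMAV", "mean(w_i |x_i|), w = 1 center / 0.5 tails", ""),
    c("MMAV2", "mean(w_i |x_i|), w = 1 center / 4i/N, 4(N-i)/N tails", ""),
    c("MYOP", "mean(|x| >= thr)", paste0("myopThreshold=", p$myopThreshold)),
    c("SSI", "sum(x^2)", "")
  )
  df <- data.frame(name = reg[, 1], formula = reg[, 2], parameter = reg[, 3])
  df[match(featureNames(config), df$name), ]
}

#' Featurize a list of swallow segments
#'
#' @param segments list of [SwallowSegment-class].
#' @param config a [featureConfig()].
#' @return data.frame with subject, label, amount, mam and the feature
#'   columns in registry order.
#' @export
featurizeSegments <- function(segments, config = featureConfig()) {
  feats <- t(vapply(segments, function(s) extractFeatures(s@samples, config),
                    numeric(length(featureNames(config)))))
  data.frame(
    subject = vapply(segments, function(s) s@subjectId, character(1)),
    label = vapply(segments, function(s) s@label, character(1)),
    amount = vapply(segments, function(s) s@amount, numeric(1)),
    mam = vapply(segments, function(s) s@mamClass, character(1)),
    feats)
}
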