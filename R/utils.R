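#' @import methods
#' @importFrom stats rnorm runif rlnorm median mad quantile sd var predict
#'   approx optim setNames ar acf fft
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib SwallowQuant, .registration = TRUE
NULL

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state.  All stochastic operations in the package go through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Derive a stream of child seeds from one parent seed (kept < 2^31).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Centered moving average with edge shrinkage (window in samples, odd-ified).
movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  if (n == 0L) return(x)
  cs <- cumsum(c(0, x))
  half <- (width - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Full-wave rectified, 50 ms moving-average sEMG envelope.
emgEnvelope <- function(x, rate, smoothMs = 50) {
  movingAverage(abs(x), round(smoothMs / 1000 * rate))
}

## Zero-phase Butterworth band-pass (edges in Hz); used for burst carriers
## and the high-frequency interference component.
bandlimitedNoise <- function(n, rate, low, high, order = 4) {
  ny <- rate / 2
  w <- c(max(low, 1) / ny, min(high, ny * 0.99) / ny)
  bf <- signal::butter(order, w, type = "pass")
  x <- stats::rnorm(n + 200)
  y <- signal::filter(bf, x)
  y <- as.numeric(y)[-seq_len(200)]  # drop filter transient
  y / max(stats::sd(y), .Machine$double.eps)
}

highpass <- function(x, rate, cutoff, order = 4) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

## Trapezoidal envelope on [0, 1] with given rise/fall fractions.
trapezoidEnvelope <- function(n, riseFrac = 0.15, fallFrac = 0.15) {
  u <- seq(0, 1, length.out = n)
  env <- rep(1, n)
  r <- u < riseFrac
  f <- u > 1 - fallFrac
  env[r] <- u[r] / riseFrac
  env[f] <- (1 - u[f]) / fallFrac
  env
}

## Maximal runs of TRUE in a logical vector -> matrix [start, end] (1-based,
## inclusive).
logicalRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

## Linear resampling of a segment to a fixed number of samples.
resampleTo <- function(x, n) {
  if (length(x) == n) return(x)
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n))$y
}

## Merge [start, end] runs separated by fewer than maxGap samples.
closeRunGaps <- function(runs, maxGap) {
  if (nrow(runs) < 2) return(runs)
  keep <- rep(TRUE, nrow(runs))
  for (i in 2:nrow(runs)) {
    prev <- max(which(keep[seq_len(i - 1)]))
    if (runs[i, "start"] - runs[prev, "end"] - 1 < maxGap) {
      runs[prev, "end"] <- runs[i, "end"]
      keep[i] <- FALSE
    }
  }
  runs[keep, , drop = FALSE]
}
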