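# Independent brute-force references, written as straight loops so they share
# no code path with the package implementations they check.

# --- forty-feature reference ------------------------------------------------

oracleFeatures <- function(x, zcThr = 0, sscThr = 0, wampThr = 0.005,
                           myopThr = 0.005, arOrder = 2, vOrder = 2,
                           tmOrder = 3) {
  n <- length(x)
  slog <- function(v, base = exp(1)) if (!is.finite(v) || v <= 0) -30
    else log(v, base = base)
  pexp <- numeric(n)
  for (i in 1:n) pexp[i] <- if (i >= 0.2 * n && i <= 0.8 * n) 0.75 else 0.5
  mu <- 0; for (i in 1:n) mu <- mu + x[i] / n
  emav <- 0; for (i in 1:n) emav <- emav + abs(x[i])^pexp[i] / n
  ewl <- 0; for (i in 2:n) ewl <- ewl + abs(x[i] - x[i - 1])^pexp[i]
  nzc <- 0
  for (i in 1:(n - 1)) {
    a <- x[i] - mu; b <- x[i + 1] - mu
    if (a * b < 0 && abs(a - b) >= zcThr) nzc <- nzc + 1
  }
  ase <- 0; for (i in 1:n) ase <- ase + sign(x[i]) * abs(x[i])^pexp[i]
  ase <- abs(ase)
  ass <- 0; for (i in 1:n) ass <- ass + sign(x[i]) * sqrt(abs(x[i]))
  ass <- abs(ass)
  msr <- 0; for (i in 1:n) msr <- msr + sqrt(abs(x[i])) / n
  tk <- 0; for (i in 2:(n - 1)) tk <- tk + x[i]^2 - x[i - 1] * x[i + 1]
  ltkeo <- slog(tk)
  s2 <- 0; for (i in 1:n) s2 <- s2 + (x[i] - mu)^2
  sdv <- sqrt(s2 / (n - 1))
  lcov <- if (sdv == 0) -30 else slog(sdv / abs(mu))
  sdd <- 0; for (i in 2:n) sdd <- sdd + (x[i] - x[i - 1])^2
  dasdv <- sqrt(sdd / (n - 1))
  ldasdv <- slog(dasdv)
  damv <- 0; for (i in 2:n) damv <- damv + abs(x[i] - x[i - 1]) / (n - 1)
  dvarv <- sdd / (n - 2)
  vord <- 0; for (i in 1:n) vord <- vord + abs(x[i])^vOrder / n
  vord <- vord^(1 / vOrder)
  tm <- 0; for (i in 1:n) tm <- tm + x[i]^tmOrder / n
  tm <- abs(tm)
  dabs <- abs(x[n] - x[1])  # telescoped sum of first differences
  # Yule-Walker AR via autocovariances and a direct solve
  ar <- rep(0, arOrder)
  if (s2 > 0) {
    r <- numeric(arOrder + 1)
    for (k in 0:arOrder) {
      acc <- 0
      for (t in 1:(n - k)) acc <- acc + (x[t] - mu) * (x[t + k] - mu)
      r[k + 1] <- acc / n
    }
    R <- matrix(0, arOrder, arOrder)
    for (i in 1:arOrder) for (j in 1:arOrder) R[i, j] <- r[abs(i - j) + 1]
    ar <- as.numeric(solve(R, r[2:(arOrder + 1)]))
  }
  madv <- 0; for (i in 1:n) madv <- madv + abs(x[i] - mu) / n
  iqrv <- unname(quantile(x, 0.75) - quantile(x, 0.25))
  varemg <- 0; for (i in 1:n) varemg <- varemg + x[i]^2 / (n - 1)
  wamp <- 0
  for (i in 1:(n - 1)) if (abs(x[i] - x[i + 1]) > wampThr) wamp <- wamp + 1
  mfl <- slog(sqrt(sdd), base = 10)
  m2 <- s2 / n
  m3 <- 0; for (i in 1:n) m3 <- m3 + (x[i] - mu)^3 / n
  m4 <- 0; for (i in 1:n) m4 <- m4 + (x[i] - mu)^4 / n
  skew <- if (m2 == 0) 0 else m3 / m2^1.5
  kurt <- if (m2 == 0) 0 else m4 / m2^2
  cov <- if (sdv == 0) 0 else sdv / abs(mu)
  ae <- 0; for (i in 1:n) ae <- ae + x[i]^2 / n
  iemg <- 0; for (i in 1:n) iemg <- iemg + abs(x[i])
  mav <- iemg / n
  ssc <- 0
  if (n >= 3) for (i in 2:(n - 1))
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > sscThr) ssc <- ssc + 1
  zc <- 0
  for (i in 1:(n - 1))
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= zcThr) zc <- zc + 1
  wl <- 0; for (i in 2:n) wl <- wl + abs(x[i] - x[i - 1])
  rms <- sqrt(ae)
  aac <- wl / (n - 1)
  logd <- if (any(abs(x) == 0)) 0 else {
    acc <- 0; for (i in 1:n) acc <- acc + log(abs(x[i])) / n; exp(acc)
  }
  w1 <- numeric(n); w2 <- numeric(n)
  for (i in 1:n) {
    w1[i] <- if (i < 0.25 * n || i > 0.75 * n) 0.5 else 1
    w2[i] <- if (i < 0.25 * n) 4 * i / n
             else if (i > 0.75 * n) 4 * (n - i) / n else 1
  }
  mmav <- 0; for (i in 1:n) mmav <- mmav + w1[i] * abs(x[i]) / n
  mmav2 <- 0; for (i in 1:n) mmav2 <- mmav2 + w2[i] * abs(x[i]) / n
  myop <- 0; for (i in 1:n) if (abs(x[i]) >= myopThr) myop <- myop + 1 / n
  ssi <- 0; for (i in 1:n) ssi <- ssi + x[i]^2
  c(EMAV = emav, EWL = ewl, NZC = nzc, ASE = ase, ASS = ass, MSR = msr,
    LTKEO = ltkeo, LCOV = lcov, LDASDV = ldasdv, DAMV = damv, DVARV = dvarv,
    VORDER = vord, TM = tm, DABS = dabs,
    setNames(ar, paste0("AR", seq_len(arOrder))),
    MAD = madv, IQR = iqrv, VAREMG = varemg, WAMP = wamp, MFL = mfl,
    SKEW = skew, KURT = kurt, COV = cov, SD = sdv, VAR = s2 / (n - 1),
    AE = ae, IEMG = iemg, MAV = mav, SSC = ssc, ZC = zc, WL = wl, RMS = rms,
    AAC = aac, DASDV = dasdv, LOG = logd, MMAV = mmav, MMAV2 = mmav2,
    MYOP = myop, SSI = ssi)
}

# --- classification / regression metric references --------------------------

oracleClassMetrics <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  acc <- 100 * sum(truth == pred) / length(truth)
  sens <- c(); spec <- c()
  for (cl in sort(unique(truth))) {
    tp <- sum(truth == cl & pred == cl); fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl); fp <- sum(truth != cl & pred == cl)
    sens <- c(sens, 100 * tp / (tp + fn))
    spec <- c(spec, 100 * tn / (tn + fp))
  }
  list(accuracy = acc, sensitivity = mean(sens), specificity = mean(spec))
}

oracleRegMetrics <- function(truth, pred) {
  n <- length(truth)
  se <- 0; ae <- 0
  for (i in 1:n) { se <- se + (pred[i] - truth[i])^2
                   ae <- ae + abs(pred[i] - truth[i]) }
  mu <- mean(truth)
  sst <- 0; for (i in 1:n) sst <- sst + (truth[i] - mu)^2
  list(rmse = sqrt(se / n), mae = ae / n, r2 = 1 - se / sst)
}

# exhaustive k-nearest-neighbour majority vote (Euclidean, smallest-class
# tie-break)
oracleKnn <- function(train, yTrain, query, k) {
  yTrain <- factor(yTrain)
  apply(query, 1, function(q) {
    d <- apply(train, 1, function(r) sqrt(sum((r - q)^2)))
    nb <- order(d)[1:k]
    votes <- table(yTrain[nb])
    names(votes)[which.max(votes)]
  })
}

# single least-squares regression stump (exhaustive split search, midpoints)
oracleStump <- function(x, y) {
  best <- list(sse = Inf)
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (cut in (v[-1] + v[-length(v)]) / 2) {
      L <- x[, j] < cut
      sse <- sum((y[L] - mean(y[L]))^2) + sum((y[!L] - mean(y[!L]))^2)
      if (sse < best$sse)
        best <- list(sse = sse, j = j, cut = cut,
                     left = mean(y[L]), right = mean(y[!L]))
    }
  }
  best
}

predictStump <- function(st, x) ifelse(x[, st$j] < st$cut, st$left, st$right)

# --- small shared fixtures --------------------------------------------------

testProfile <- function(seed = 42, id = "T1") sampleSubjectProfile(id, seed)

# compact protocol for fast signal-level tests
smallProtocol <- function() IngestProtocol(nSipsPerVolume = 1L,
                                           nBolusesPerCell = 1L,
                                           durationSec = 120)

# match each true event to the nearest detected segment midpoint
matchEvents <- function(session, segments, tolSec = 0.25) {
  ev <- sessionEvents(session)
  mids <- vapply(segments, function(g)
    (g@startSample + g@endSample) / 2 / g@rate, numeric(1))
  mam <- vapply(segments, mamClass, character(1))
  trueMid <- (ev$onset + ev$offset) / 2
  ok <- logical(nrow(ev)); okMam <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    j <- which.min(abs(mids - trueMid[i]))
    ok[i] <- abs(mids[j] - trueMid[i]) <= tolSec
    okMam[i] <- ok[i] &&
      (mam[j] == "high") == (ev$kind[i] == "bite")
  }
  list(matched = ok, matchedMam = okMam)
}
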