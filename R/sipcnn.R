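## Raw-signal 1D convolutional classifier for water sip volume.
##
## Architecture: 5 conv blocks (kernel 5, same padding, output channels
## 32/32/32/64/64, each followed by batch normalization, ReLU and 1x2 max
## pooling on time), flatten, two ReLU dense layers, 4-way softmax output
## (classes 10/20/30/40 ml).  Implemented directly on BLAS matrix products
## (im2col layout); training is plain mini-batch cross-entropy with Adam,
## deterministic under a fixed seed in single-threaded execution.
##
## Batched activations are stored sample-major: a (batch*length) x channels
## matrix whose rows b*(1..L) hold sample b.

#' Build the sip-volume CNN
#'
#' Initializes the fixed architecture: five 1D convolutional blocks with
#' kernel size 5 and output channels 32, 32, 32, 64, 64, each followed by
#' batch normalization and 1x2 max pooling on time, then two dense layers
#' and a 4-way output.  He-initialized weights, deterministic under the
#' seed.
#'
#' @param inputLength input length in samples; must be divisible by 32 and
#'   at least 160 (the kernel footprint across the five pooling stages).
#' @param seed RNG seed for the initialization.
#' @param denseUnits widths of the two dense layers.
#' @param normalize divide each segment by its RMS before the network.
#' @param dropout training-time dropout probability on the dense hidden
#'   layers (inverted dropout; inference is unaffected).
#' @return list of class "sipCnn".
#' @export
buildSipCnn <- function(inputLength = 4096L, seed = 1L,
                        denseUnits = c(64L, 32L), normalize = FALSE,
                        dropout = 0) {
  inputLength <- as.integer(inputLength)
  if (inputLength %% 32L != 0L || inputLength < 160L)
    stop("inputLength must be a multiple of 32 and >= 160")
  channels <- c(32L, 32L, 32L, 64L, 64L)
  withSeed(seed, {
    conv <- list(); Cin <- 1L
    for (l in seq_along(channels)) {
      Cout <- channels[l]
      conv[[l]] <- list(
        W = matrix(stats::rnorm(5L * Cin * Cout, 0, sqrt(2 / (5 * Cin))),
                   5L * Cin, Cout),
        b = rep(0, Cout), gamma = rep(1, Cout), beta = rep(0, Cout),
        rm = rep(0, Cout), rv = rep(1, Cout))
      Cin <- Cout
    }
    flat <- (inputLength %/% 32L) * 64L
    sizes <- c(flat, denseUnits, 4L)
    dense <- lapply(seq_len(length(sizes) - 1L), function(j) {
      list(W = matrix(stats::rnorm(sizes[j] * sizes[j + 1L], 0,
                                   sqrt(2 / sizes[j])), sizes[j], sizes[j + 1L]),
           b = rep(0, sizes[j + 1L]))
    })
    structure(list(inputLength = inputLength, channels = channels,
                   kernel = 5L, denseUnits = as.integer(denseUnits),
                   nClasses = 4L, conv = conv, dense = dense,
                   classes = c(10, 20, 30, 40), normalize = normalize,
                   dropout = dropout, seed = as.integer(seed)),
              class = "sipCnn")
  })
}

#' Layer-by-layer shape trace of the CNN
#'
#' @param model a "sipCnn".
#' @return data.frame(layer, type, outLength, outChannels) for an
#'   architecture audit.
#' @export
architectureTrace <- function(model) {
  L <- model$inputLength
  rows <- data.frame(layer = "input", type = "input", outLength = L,
                     outChannels = 1L)
  for (l in seq_along(model$channels)) {
    C <- model$channels[l]
    rows <- rbind(rows,
      data.frame(layer = paste0("conv", l),
                 type = "conv1d(k=5) + batchnorm + relu",
                 outLength = L, outChannels = C),
      data.frame(layer = paste0("pool", l), type = "maxpool(1x2)",
                 outLength = L %/% 2L, outChannels = C))
    L <- L %/% 2L
  }
  flat <- L * model$channels[length(model$channels)]
  rows <- rbind(rows,
    data.frame(layer = "flatten", type = "flatten", outLength = flat,
               outChannels = 1L))
  for (j in seq_along(model$denseUnits))
    rows <- rbind(rows, data.frame(layer = paste0("dense", j),
                                   type = "dense + relu",
                                   outLength = model$denseUnits[j],
                                   outChannels = 1L))
  rbind(rows, data.frame(layer = "output", type = "dense + softmax",
                         outLength = model$nClasses, outChannels = 1L))
}

## Full forward pass; with cache = TRUE keeps what backprop needs.
## The fused conv + batchnorm + ReLU + maxpool block runs in compiled code.
.cnnForward <- function(model, Xb, training, cache = FALSE) {
  B <- nrow(Xb); L <- model$inputLength
  X <- matrix(as.vector(t(Xb)), B * L, 1L)  # sample-major rows
  caches <- list()
  for (l in seq_along(model$conv)) {
    p <- model$conv[[l]]
    blk <- sq_conv_block_fwd(X, B, L, p$W, p$b, p$gamma, p$beta, p$rm, p$rv,
                             training, 0.1, 1e-5)
    if (training) {
      model$conv[[l]]$rm <- drop(blk$rm)
      model$conv[[l]]$rv <- drop(blk$rv)
    }
    if (cache)
      caches[[l]] <- list(X = X, Zn = blk$Zn, inv = drop(blk$inv), L = L)
    X <- blk$P
    L <- L %/% 2L
  }
  Fm <- matrix(0, B, L * ncol(X))
  for (b in seq_len(B))
    Fm[b, ] <- as.vector(X[(b - 1L) * L + seq_len(L), , drop = FALSE])
  H <- Fm
  hs <- list()
  nd <- length(model$dense)
  p <- if (is.null(model$dropout)) 0 else model$dropout
  for (j in seq_len(nd)) {
    Z <- H %*% model$dense[[j]]$W
    Z <- Z + rep(model$dense[[j]]$b, each = nrow(Z))
    if (j < nd) {
      A <- Z * (Z > 0)
      mask <- NULL
      if (training && p > 0) {  # inverted dropout
        mask <- matrix((stats::runif(length(A)) >= p) / (1 - p),
                       nrow(A), ncol(A))
        A <- A * mask
      }
      if (cache) hs[[j]] <- list(H = H, Z = Z, mask = mask)
      H <- A
    } else {
      if (cache) hs[[j]] <- list(H = H, Z = Z, mask = NULL)
      H <- Z
    }
  }
  list(logits = H, caches = caches, hs = hs, Fm = Fm, model = model,
       lastL = L)
}

.softmax <- function(Z) {
  e <- exp(Z - apply(Z, 1, max))
  e / rowSums(e)
}

## One backward pass; returns gradients in the same structure as the params.
.cnnBackward <- function(model, fw, Y) {
  B <- nrow(Y)
  P <- .softmax(fw$logits)
  dZ <- (P - Y) / B
  nd <- length(model$dense)
  gDense <- vector("list", nd)
  for (j in rev(seq_len(nd))) {
    hc <- fw$hs[[j]]
    gDense[[j]] <- list(dW = crossprod(hc$H, dZ), db = colSums(dZ))
    dH <- dZ %*% t(model$dense[[j]]$W)
    if (j > 1L) {
      prev <- fw$hs[[j - 1L]]
      if (!is.null(prev$mask)) dH <- dH * prev$mask
      dZ <- dH * (prev$Z > 0)
    } else dF <- dH
  }
  L <- fw$lastL
  C <- model$channels[length(model$channels)]
  dX <- matrix(0, B * L, C)
  for (b in seq_len(B))
    dX[(b - 1L) * L + seq_len(L), ] <- matrix(dF[b, ], L, C)
  gConv <- vector("list", length(model$conv))
  for (l in rev(seq_along(model$conv))) {
    cc <- fw$caches[[l]]
    p <- model$conv[[l]]
    cb <- sq_conv_block_bwd(dX, cc$X, cc$Zn, cc$inv, p$gamma, p$beta, p$W,
                            B, cc$L)
    gConv[[l]] <- list(dW = cb$dW, db = drop(cb$db),
                       dgamma = drop(cb$dgamma), dbeta = drop(cb$dbeta))
    dX <- cb$dX
  }
  list(conv = gConv, dense = gDense)
}

## Pad (right, zeros) or linearly resample a segment to the input length.
.prepSegment <- function(x, inputLength, normalize) {
  if (normalize) {
    r <- sqrt(mean(x^2))
    if (r > 0) x <- x / r
  }
  n <- length(x)
  if (n >= inputLength) resampleTo(x, inputLength)
  else c(x, rep(0, inputLength - n))
}

#' Prepare sip segments for the CNN
#'
#' Segments shorter than the input length are zero-padded on the right
#' (preserving the duration cue); longer ones are linearly resampled down.
#'
#' @param segments list of numeric vectors or [SwallowSegment-class]s.
#' @param model a "sipCnn" (supplies input length and normalization flag).
#' @return matrix, one row per segment.
#' @export
prepareSipInput <- function(segments, model) {
  xs <- lapply(segments, function(s)
    if (is(s, "SwallowSegment")) s@samples else as.numeric(s))
  t(vapply(xs, .prepSegment, numeric(model$inputLength),
           inputLength = model$inputLength, normalize = model$normalize))
}

.adamInit <- function(params) lapply(params, function(p) {
  lapply(p, function(v) list(m = 0 * v, v = 0 * v))
})

.adamStep <- function(value, grad, st, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(value = value - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the sip-volume CNN
#'
#' Mini-batch cross-entropy training with Adam; deterministic given the seed
#' under single-threaded execution.
#'
#' @param model a "sipCnn" from [buildSipCnn()].
#' @param X input matrix from [prepareSipInput()].
#' @param labels sip volumes (ml), each one of 10/20/30/40.
#' @param epochs training epochs.
#' @param batchSize mini-batch size.
#' @param lr Adam learning rate.
#' @param seed RNG seed for shuffling and augmentation.
#' @param augmentShift maximum random right-shift (samples) applied to each
#'   training segment per epoch; 0 disables.  Shifting dislodges
#'   position-memorized solutions and forces duration-based features.
#' @param verbose print per-epoch training accuracy.
#' @return The trained "sipCnn" with a `history` data.frame
#'   (epoch, loss, accuracy).
#' @export
trainSipCnn <- function(model, X, labels, epochs = 20L, batchSize = 32L,
                        lr = 1e-3, seed = 1L, augmentShift = 0L,
                        verbose = FALSE) {
  yIdx <- match(labels, model$classes)
  if (anyNA(yIdx)) stop("labels must be one of ", paste(model$classes,
                                                        collapse = "/"))
  n <- nrow(X)
  L <- model$inputLength
  Y <- matrix(0, n, model$nClasses)
  Y[cbind(seq_len(n), yIdx)] <- 1
  adam <- list(conv = .adamInit(model$conv), dense = .adamInit(model$dense))
  t <- 0
  hist <- NULL
  ## one seeded stream drives shuffling, augmentation and dropout masks
  withSeed(seed, {
  rng <- list(
    ord = lapply(seq_len(epochs), function(e) sample.int(n)),
    shift = if (augmentShift > 0)
      matrix(sample.int(augmentShift + 1L, n * epochs, replace = TRUE) - 1L,
             n, epochs) else NULL)
  for (ep in seq_len(epochs)) {
    idx <- rng$ord[[ep]]
    lossSum <- 0; correct <- 0
    for (start in seq(1L, n, by = batchSize)) {
      sel <- idx[start:min(start + batchSize - 1L, n)]
      Xb <- X[sel, , drop = FALSE]
      if (!is.null(rng$shift)) {
        for (b in seq_along(sel)) {
          sh <- rng$shift[sel[b], ep]
          if (sh > 0)
            Xb[b, ] <- c(rep(0, sh), Xb[b, seq_len(L - sh)])
        }
      }
      fw <- .cnnForward(model, Xb, training = TRUE,
                        cache = TRUE)
      model <- fw$model  # updated running BN stats
      P <- .softmax(fw$logits)
      lossSum <- lossSum - sum(log(pmax(P[cbind(seq_along(sel),
                                                yIdx[sel])], 1e-12)))
      correct <- correct + sum(max.col(P) == yIdx[sel])
      gr <- .cnnBackward(model, fw, Y[sel, , drop = FALSE])
      t <- t + 1
      for (l in seq_along(model$conv)) {
        for (nm in c("W", "b", "gamma", "beta")) {
          gnm <- if (nm %in% c("W", "b")) paste0("d", nm) else paste0("d", nm)
          up <- .adamStep(model$conv[[l]][[nm]], gr$conv[[l]][[gnm]],
                          adam$conv[[l]][[nm]], lr, t)
          model$conv[[l]][[nm]] <- up$value
          adam$conv[[l]][[nm]] <- up$st
        }
      }
      for (j in seq_along(model$dense)) {
        for (nm in c("W", "b")) {
          up <- .adamStep(model$dense[[j]][[nm]], gr$dense[[j]][[paste0("d", nm)]],
                          adam$dense[[j]][[nm]], lr, t)
          model$dense[[j]][[nm]] <- up$value
          adam$dense[[j]][[nm]] <- up$st
        }
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = lossSum / n,
                                   accuracy = correct / n))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f", ep, lossSum / n,
                      correct / n))
  }
  })
  model$history <- hist
  model
}

#' @rdname trainSipCnn
#' @return `predictSipCnn`: numeric vector of predicted volumes (ml).
#' @export
predictSipCnn <- function(model, X, batchSize = 64L) {
  preds <- integer(0)
  for (start in seq(1L, nrow(X), by = batchSize)) {
    sel <- start:min(start + batchSize - 1L, nrow(X))
    fw <- .cnnForward(model, X[sel, , drop = FALSE], training = FALSE)
    preds <- c(preds, max.col(.softmax(fw$logits)))
  }
  model$classes[preds]
}

#' Run the sip-volume CNN study on a synthetic cohort
#'
#' Generates per-subject water-sip bursts (volumes balanced within subject),
#' trains the CNN under an among-subject (AS) holdout or a cross-subject
#' (CS) subject-disjoint holdout, and reports the held-out accuracy.
#'
#' With `separable = TRUE` the cohort is generated under the separable
#' condition: the per-volume amplitude spread is widened (envelope factor
#' 0.4 + 0.03 * ml instead of the session generator's 0.7 + 0.0125 * ml) and
#' the subjects' sEMG gains and paces are equalized, so the four volumes
#' have well-separated burst energies and durations cohort-wide.  With `separable = FALSE` the
#' session generator's full inter-subject variability (lognormal gain,
#' subject carrier bands, pace) is kept - the condition under which the
#' cross-subject scheme is measurably harder than the among-subject scheme.
#'
#' @param nSubjects subjects in the cohort.
#' @param sipsPerSubject sips per subject (balanced over the four volumes).
#' @param scheme "AS" or "CS".
#' @param epochs training epochs.
#' @param seed RNG seed for cohort, split, initialization and training.
#' @param inputLength CNN input length, samples.
#' @param shuffleLabels permute the training+test labels first (chance-level
#'   control).
#' @param holdoutFrac test fraction (AS: stratified by subject; CS: the
#'   closest whole number of held-out subjects).
#' @param lr Adam learning rate for the training run.
#' @param augmentShift training-time random shift range, samples.
#' @param separable widen the per-volume amplitude spread (see Details).
#' @return list(accuracy, model, nTrain, nTest).
#' @export
runSipCnnStudy <- function(nSubjects = 10L, sipsPerSubject = 20L,
                           scheme = c("AS", "CS"), epochs = 20L, seed = 1L,
                           inputLength = 4096L, shuffleLabels = FALSE,
                           holdoutFrac = 0.2, lr = 1e-3,
                           augmentShift = 0L, separable = TRUE) {
  scheme <- match.arg(scheme)
  seeds <- childSeeds(seed, 3L + nSubjects)
  vols <- c(10, 20, 30, 40)
  segs <- list(); labs <- numeric(0); subj <- character(0)
  for (s in seq_len(nSubjects)) {
    prof <- sampleSubjectProfile(sprintf("S%02d", s), seeds[3L + s])
    genProf <- prof
    if (separable) genProf@durGain <- 1  # pace equalized cohort-wide
    bs <- childSeeds(seeds[3L + s], sipsPerSubject)
    for (i in seq_len(sipsPerSubject)) {
      ml <- vols[(i - 1L) %% 4L + 1L]
      b <- synthSwallowBurst("water", ml, genProf, seed = bs[i])
      if (separable)  # wide-spread amplitudes, gain equalized cohort-wide
        b <- b * (0.4 + 0.03 * ml) / ((0.7 + 0.0125 * ml) * prof@emgGain)
      segs[[length(segs) + 1L]] <- b
      labs <- c(labs, ml)
      subj <- c(subj, prof@subjectId)
    }
  }
  if (shuffleLabels) labs <- withSeed(seeds[1], sample(labs))
  model <- buildSipCnn(inputLength, seed = seeds[2])
  X <- prepareSipInput(segs, model)
  if (scheme == "AS") {
    sp <- holdoutSplit(paste(subj, labs), frac = 1 - holdoutFrac,
                       seed = seeds[1])
  } else {
    subjects <- unique(subj)
    nTe <- max(1L, round(holdoutFrac * length(subjects)))
    teSubj <- withSeed(seeds[1], sample(subjects, nTe))
    sp <- list(train = which(!subj %in% teSubj),
               test = which(subj %in% teSubj))
  }
  model <- trainSipCnn(model, X[sp$train, , drop = FALSE], labs[sp$train],
                       epochs = epochs, seed = seeds[3], lr = lr,
                       augmentShift = augmentShift)
  pred <- predictSipCnn(model, X[sp$test, , drop = FALSE])
  list(accuracy = mean(pred == labs[sp$test]), model = model,
       nTrain = length(sp$train), nTest = length(sp$test))
}
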