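## Solid-bolus type classification, weight regression, the two cascade
## orderings, and water-sip volume regression.
##
## Printed model configurations: KNN with K = 5 and Euclidean distance; SVM
## with C = 1 and an RBF kernel; decision trees split on entropy, internal
## nodes need >= 2 samples and grow until leaves are pure.  Distance- and
## kernel-based models (KNN, SVM, the networks) see per-fit z-scored
## features (fit on training data only); trees and tree ensembles see raw
## features.

#' Classifier specification
#'
#' @param family "KNN", "SVM" or "DT".
#' @param knnK neighbours (KNN).
#' @param svmC soft-margin cost (SVM).
#' @param seed RNG seed for any stochastic fitting.
#' @return list of class "ClassifierSpec".
#' @export
classifierSpec <- function(family = c("KNN", "SVM", "DT"), knnK = 5L,
                           svmC = 1, seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, knnK = as.integer(knnK), svmC = svmC,
                 seed = as.integer(seed)), class = "ClassifierSpec")
}

#' Regressor specification
#'
#' Families: decision tree (DT), extra trees (ET), AdaBoost.R2 (AB),
#' least-squares gradient boosting (GB), XGBoost (XGB), leaf-wise
#' histogram boosting (LGB), random forest (RF), epsilon-SVR (SVM),
#' Gaussian-process regression with an RBF + white-noise kernel (GPR), and
#' the feed-forward network (NN) trained by Levenberg-Marquardt ("LM") or
#' Bayesian regularization ("BR").
#'
#' @param family one of the above.
#' @param nTrees ensemble size for the tree ensembles.
#' @param maxDepth base-learner depth for AB/GB.
#' @param nnHidden,nnEpochs,nnTrainer,nnOutput network configuration: hidden
#'   units, training epochs, "LM" or "BR", output activation "relu"
#'   (linear-rectified) or "linear".
#' @param seed RNG seed.
#' @return list of class "RegressorSpec".
#' @export
regressorSpec <- function(family = c("ET", "DT", "AB", "GB", "XGB", "LGB",
                                     "RF", "SVM", "GPR", "NN"),
                          nTrees = 100L, maxDepth = 3L, nnHidden = 50L,
                          nnEpochs = 1000L, nnTrainer = c("LM", "BR"),
                          nnOutput = c("relu", "linear"), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, nTrees = as.integer(nTrees),
                 maxDepth = as.integer(maxDepth), nnHidden = as.integer(nnHidden),
                 nnEpochs = as.integer(nnEpochs),
                 nnTrainer = match.arg(nnTrainer),
                 nnOutput = match.arg(nnOutput), seed = as.integer(seed)),
            class = "RegressorSpec")
}

.zfit <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.zapply <- function(x, z) scale(as.matrix(x), center = z$center, scale = z$scale)

#' Fit a bolus-type classifier
#'
#' @param x feature matrix or data.frame (numeric columns).
#' @param y class labels (factor or character).
#' @param spec a [classifierSpec()].
#' @return Fitted classifier (class "sqClassifier"); predict with
#'   [predictClassifier()].
#' @export
fitClassifier <- function(x, y, spec = classifierSpec()) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need >= 2 classes to fit a classifier")
  x <- as.matrix(x)
  fit <- switch(spec$family,
    KNN = {
      z <- .zfit(x)
      list(train = .zapply(x, z), y = y, z = z, k = spec$knnK)
    },
    SVM = {
      z <- .zfit(x)
      xs <- .zapply(x, z)
      gamma <- 1 / (ncol(xs) * max(mean(apply(xs, 2, stats::var)), 1e-12))
      m <- withSeed(spec$seed,
        e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                   cost = spec$svmC, gamma = gamma, scale = FALSE))
      list(model = m, z = z)
    },
    DT = {
      df <- data.frame(.y = y, x)
      ## entropy splits, >= 2 samples per internal node, grow to pure leaves
      list(model = rpart::rpart(.y ~ ., df, method = "class",
             parms = list(split = "information"),
             control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                            cp = 0, xval = 0, maxdepth = 30)))
    })
  structure(c(fit, list(family = spec$family, levels = levels(y))),
            class = "sqClassifier")
}

#' @rdname fitClassifier
#' @param object a fitted "sqClassifier".
#' @param newdata feature matrix/data.frame.
#' @export
predictClassifier <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  out <- switch(object$family,
    KNN = {
      xs <- .zapply(newdata, object$z)
      tr <- object$train
      apply(xs, 1, function(q) {
        d <- sqrt(colSums((t(tr) - q)^2))
        nb <- order(d)[seq_len(object$k)]
        tab <- table(object$y[nb])
        ## deterministic: ties broken by smallest class index
        names(tab)[which.max(tab)]
      })
    },
    SVM = as.character(predict(object$model, .zapply(newdata, object$z))),
    DT = as.character(predict(object$model, data.frame(newdata),
                              type = "class")))
  factor(out, levels = object$levels)
}

## -- hand-written ensemble regressors ---------------------------------------

## Least-squares gradient boosting on rpart base learners.
.fitGB <- function(x, y, nTrees, maxDepth, shrinkage = 0.1) {
  df <- data.frame(x)
  f0 <- mean(y)
  fit <- rep(f0, length(y))
  trees <- vector("list", nTrees)
  ctrl <- rpart::rpart.control(maxdepth = maxDepth, minsplit = 2,
                               minbucket = 1, cp = 0, xval = 0)
  for (m in seq_len(nTrees)) {
    df$.r <- y - fit
    tr <- rpart::rpart(.r ~ . - .r, df, method = "anova", control = ctrl)
    trees[[m]] <- tr
    fit <- fit + shrinkage * predict(tr, df)
  }
  list(f0 = f0, trees = trees, shrinkage = shrinkage)
}

.predictGB <- function(gb, x) {
  df <- data.frame(x)
  p <- rep(gb$f0, nrow(df))
  for (tr in gb$trees) p <- p + gb$shrinkage * predict(tr, df)
  p
}

## AdaBoost.R2 (linear loss) on rpart base learners; prediction is the
## weighted median of the base predictions.
.fitAB <- function(x, y, nTrees, maxDepth, seed) {
  df <- data.frame(x)
  n <- length(y)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric()
  ctrl <- rpart::rpart.control(maxdepth = maxDepth, minsplit = 2,
                               minbucket = 1, cp = 0, xval = 0)
  withSeed(seed, for (m in seq_len(nTrees)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    dfm <- df[idx, , drop = FALSE]; dfm$.y <- y[idx]
    tr <- rpart::rpart(.y ~ . - .y, dfm, method = "anova", control = ctrl)
    pred <- predict(tr, df)
    err <- abs(pred - y)
    D <- max(err)
    if (D <= 0) { trees[[m]] <- tr; betas[m] <- 1e-10; break }
    L <- err / D
    ebar <- sum(w * L)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    w <- w * beta^(1 - L)
    w <- w / sum(w)
    trees[[m]] <- tr
    betas[m] <- beta
  })
  list(trees = trees, betas = betas)
}

.predictAB <- function(ab, x) {
  df <- data.frame(x)
  if (!length(ab$trees)) stop("empty AdaBoost ensemble")
  P <- vapply(ab$trees, function(tr) predict(tr, df), numeric(nrow(df)))
  P <- matrix(P, nrow = nrow(df))
  lw <- log(1 / pmax(ab$betas, 1e-300))
  apply(P, 1, function(p) {  # weighted median
    o <- order(p)
    cw <- cumsum(lw[o])
    p[o][which(cw >= 0.5 * sum(lw))[1]]
  })
}

## Gaussian-process regression, RBF + white noise, hyperparameters by
## marginal-likelihood optimization.
.fitGPR <- function(x, y, seed) {
  if (stats::var(y) == 0) stop("constant targets: degenerate GPR kernel")
  z <- .zfit(x)
  xs <- .zapply(x, z)
  ym <- mean(y); ys <- stats::sd(y)
  yc <- (y - ym) / ys
  d2 <- as.matrix(stats::dist(xs))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  nll <- function(par) {
    ell2 <- exp(par[1]); sf2 <- exp(par[2]); sn2 <- exp(par[3])
    K <- sf2 * exp(-d2 / (2 * ell2)) + diag(sn2, nrow(xs))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    a <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * a) + sum(log(diag(ch))) + 0.5 * nrow(xs) * log(2 * pi)
  }
  opt <- withSeed(seed,
    stats::optim(c(log(med), 0, log(0.01)), nll, method = "L-BFGS-B",
                 lower = c(log(med) - 8, -8, -12), upper = c(log(med) + 8, 6, 2)))
  ell2 <- exp(opt$par[1]); sf2 <- exp(opt$par[2]); sn2 <- exp(opt$par[3])
  K <- sf2 * exp(-d2 / (2 * ell2)) + diag(sn2, nrow(xs))
  alpha <- solve(K, yc)
  list(z = z, xs = xs, alpha = alpha, ell2 = ell2, sf2 = sf2,
       ym = ym, ys = ys)
}

.predictGPR <- function(gp, x) {
  q <- .zapply(x, gp$z)
  cross <- apply(q, 1, function(r) {
    gp$sf2 * exp(-colSums((t(gp$xs) - r)^2) / (2 * gp$ell2))
  })
  drop(t(cross) %*% gp$alpha) * gp$ys + gp$ym
}

#' Fit a bolus-weight / sip-volume regressor
#'
#' @param x feature matrix or data.frame.
#' @param y numeric targets (>= 2 distinct values).
#' @param spec a [regressorSpec()].
#' @return Fitted regressor (class "sqRegressor"); predict with
#'   [predictRegressor()].
#' @export
fitRegressor <- function(x, y, spec = regressorSpec()) {
  if (length(unique(y)) < 2 && spec$family == "GPR")
    stop("constant targets: degenerate GPR kernel")
  if (length(unique(y)) < 2 && spec$family != "GPR")
    message("constant targets; fitted regressor is constant")
  x <- as.matrix(x)
  df <- data.frame(x)
  fit <- switch(spec$family,
    DT = list(model = rpart::rpart(.y ~ ., cbind(df, .y = y), method = "anova",
      control = rpart::rpart.control(minsplit = 5, cp = 1e-4, xval = 0))),
    ET = list(model = ranger::ranger(
      x = df, y = y, num.trees = spec$nTrees, splitrule = "extratrees",
      num.random.splits = 1, replace = FALSE, sample.fraction = 1,
      min.node.size = 1, mtry = ncol(df), seed = spec$seed,
      num.threads = 1)),
    RF = list(model = ranger::ranger(
      x = df, y = y, num.trees = spec$nTrees, seed = spec$seed,
      num.threads = 1)),
    AB = list(model = .fitAB(x, y, spec$nTrees, spec$maxDepth, spec$seed)),
    GB = list(model = .fitGB(x, y, spec$nTrees, spec$maxDepth)),
    XGB = list(model = xgboost::xgboost(
      x, y, nrounds = spec$nTrees, learning_rate = 0.1, max_depth = 6,
      nthreads = 1, verbosity = 0, seed = spec$seed)),
    LGB = list(model = xgboost::xgboost(
      x, y, nrounds = spec$nTrees, learning_rate = 0.1, tree_method = "hist",
      grow_policy = "lossguide", max_leaves = 31L, max_depth = 0L,
      nthreads = 1, verbosity = 0, seed = spec$seed)),
    SVM = {
      z <- .zfit(x)
      xs <- .zapply(x, z)
      gamma <- 1 / (ncol(xs) * max(mean(apply(xs, 2, stats::var)), 1e-12))
      list(model = withSeed(spec$seed,
        e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
                   cost = 1, gamma = gamma, scale = FALSE)), z = z)
    },
    GPR = list(model = .fitGPR(x, y, spec$seed)),
    NN = {
      z <- .zfit(x)
      xs <- .zapply(x, z)
      net <- if (spec$nnTrainer == "LM")
        trainFfnn(xs, y, hidden = spec$nnHidden, epochs = spec$nnEpochs,
                  outputActivation = spec$nnOutput, seed = spec$seed)
      else
        trainFfnnBr(xs, y, hidden = spec$nnHidden, epochs = spec$nnEpochs,
                    outputActivation = spec$nnOutput, seed = spec$seed)
      list(model = net, z = z)
    })
  structure(c(fit, list(family = spec$family)), class = "sqRegressor")
}

#' @rdname fitRegressor
#' @param object a fitted "sqRegressor".
#' @param newdata feature matrix/data.frame.
#' @export
predictRegressor <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  df <- data.frame(newdata)
  switch(object$family,
    DT = as.numeric(predict(object$model, df)),
    ET = ,
    RF = predict(object$model, df, num.threads = 1)$predictions,
    AB = .predictAB(object$model, newdata),
    GB = .predictGB(object$model, newdata),
    XGB = ,
    LGB = as.numeric(predict(object$model, newdata)),
    SVM = as.numeric(predict(object$model, .zapply(newdata, object$z))),
    GPR = .predictGPR(object$model, newdata),
    NN = as.numeric(predictFfnn(object$model, .zapply(newdata, object$z))))
}

#' Bin a bolus weight into the volume groups
#'
#' Small below 4.5 g, intermediate in [4.5, 7.5), large at and above 7.5 g
#' (half-open boundary convention).
#'
#' @param weight numeric weight(s), g.
#' @return factor with levels low/intermediate/high.
#' @export
volumeGroup <- function(weight) {
  stopifnot(all(is.finite(weight)))
  cut(weight, c(-Inf, 4.5, 7.5, Inf), labels = c("low", "intermediate", "high"),
      right = FALSE)
}

#' Fit a cascade model for solid bolus type and weight
#'
#' `classify_first`: one material classifier, then one per-material weight
#' regressor (the material is known at the regression stage).
#' `regress_first`: one global weight regressor, then one material
#' classifier per volume group of the *predicted* weight.
#'
#' @param x feature matrix of solid-bolus segments.
#' @param material material labels.
#' @param weight bolus weights, g.
#' @param ordering "classify_first" or "regress_first".
#' @param cSpec a [classifierSpec()].
#' @param rSpec a [regressorSpec()].
#' @return list of class "sqCascade".
#' @export
cascadeFit <- function(x, material, weight,
                       ordering = c("classify_first", "regress_first"),
                       cSpec = classifierSpec(), rSpec = regressorSpec()) {
  ordering <- match.arg(ordering)
  material <- factor(material)
  x <- as.matrix(x)
  if (nlevels(droplevels(material)) == 1) {
    ## degenerate single-class cascade: constant material, one regressor
    return(structure(list(ordering = "degenerate",
                          material = as.character(material[1]),
                          regressor = fitRegressor(x, weight, rSpec)),
                     class = "sqCascade"))
  }
  if (ordering == "classify_first") {
    cls <- fitClassifier(x, material, cSpec)
    regs <- lapply(levels(material), function(m) {
      sel <- material == m
      fitRegressor(x[sel, , drop = FALSE], weight[sel], rSpec)
    })
    names(regs) <- levels(material)
    out <- list(ordering = ordering, classifier = cls, regressors = regs)
  } else {
    reg <- fitRegressor(x, weight, rSpec)
    grp <- volumeGroup(predictRegressor(reg, x))
    clss <- lapply(levels(grp), function(g) {
      sel <- grp == g
      if (sum(sel) < 2 || nlevels(droplevels(material[sel])) < 2) NULL
      else fitClassifier(x[sel, , drop = FALSE], material[sel], cSpec)
    })
    names(clss) <- levels(grp)
    fallback <- fitClassifier(x, material, cSpec)
    out <- list(ordering = ordering, regressor = reg, classifiers = clss,
                fallback = fallback, levels = levels(material))
  }
  structure(out, class = "sqCascade")
}

#' @rdname cascadeFit
#' @param object a fitted "sqCascade".
#' @param newdata feature matrix.
#' @return `cascadePredict`: data.frame(material, weight).
#' @export
cascadePredict <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (object$ordering == "degenerate") {
    return(data.frame(material = rep(object$material, nrow(newdata)),
                      weight = predictRegressor(object$regressor, newdata)))
  }
  if (object$ordering == "classify_first") {
    mat <- predictClassifier(object$classifier, newdata)
    w <- numeric(nrow(newdata))
    for (m in levels(mat)) {
      sel <- mat == m
      if (any(sel))
        w[sel] <- predictRegressor(object$regressors[[m]],
                                   newdata[sel, , drop = FALSE])
    }
  } else {
    w <- predictRegressor(object$regressor, newdata)
    grp <- volumeGroup(w)
    mat <- factor(rep(NA_character_, nrow(newdata)), levels = object$levels)
    for (g in levels(grp)) {
      sel <- grp == g
      if (!any(sel)) next
      cls <- object$classifiers[[g]]
      if (is.null(cls)) cls <- object$fallback
      mat[sel] <- predictClassifier(cls, newdata[sel, , drop = FALSE])
    }
  }
  data.frame(material = mat, weight = w)
}

#' Direct sip-volume regression from the forty features
#'
#' Convenience wrapper around [fitRegressor()] for low-MAM (water) segments
#' with targets in the admissible sip volumes.
#'
#' @param x feature matrix of water-sip segments.
#' @param volumes sip volumes, ml.
#' @param spec a [regressorSpec()].
#' @return A fitted "sqRegressor".
#' @export
sipVolumeRegress <- function(x, volumes, spec = regressorSpec("NN")) {
  fitRegressor(x, volumes, spec)
}
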