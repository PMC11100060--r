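## Among-subject / cross-subject fivefold validation and the metric set.

#' Build a fivefold cross-validation plan
#'
#' AS (among-subject): samples are stratified by subject (and by class when
#' given), shuffled and dealt round-robin, so every subject contributes to
#' the training and test side of every fold where possible.  CS
#' (cross-subject): subjects are shuffled and partitioned into k groups;
#' each group's samples form one test fold, so train and test subjects are
#' disjoint within every fold.
#'
#' @param subjects per-sample subject identifiers.
#' @param scheme "AS" or "CS".
#' @param k number of folds.
#' @param seed RNG seed (plans are deterministic given it).
#' @param classes optional per-sample class labels for AS stratification.
#' @return A [FoldPlan-class].
#' @export
makeFolds <- function(subjects, scheme = c("AS", "CS"), k = 5L, seed = 1L,
                      classes = NULL) {
  scheme <- match.arg(scheme)
  subjects <- as.character(subjects)
  n <- length(subjects)
  k <- as.integer(k)
  fold <- integer(n)
  if (scheme == "AS") {
    strat <- if (is.null(classes)) subjects
             else paste(subjects, classes, sep = "\r")
    withSeed(seed, for (g in unique(strat)) {
      idx <- sample(which(strat == g))
      fold[idx] <- (seq_along(idx) - 1L) %% k + 1L
    })
  } else {
    subj <- unique(subjects)
    if (length(subj) < k)
      stop("cross-subject folds need at least k subjects")
    subj <- withSeed(seed, sample(subj))
    grp <- (seq_along(subj) - 1L) %% k + 1L
    fold <- grp[match(subjects, subj)]
  }
  folds <- lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
  new("FoldPlan", scheme = scheme, k = k, folds = folds,
      seed = as.integer(seed))
}

#' 80-20 holdout split
#'
#' Deterministic stratified-by-subject holdout (the bites-data split mode):
#' within every subject the shuffled samples are divided `frac` / 1-`frac`
#' between train and test.
#'
#' @param subjects per-sample subject identifiers (or a bare count for an
#'   unstratified split).
#' @param frac training fraction.
#' @param seed RNG seed.
#' @return list(train, test) index vectors.
#' @export
holdoutSplit <- function(subjects, frac = 0.8, seed = 1L) {
  if (length(subjects) == 1L && is.numeric(subjects)) {
    n <- as.integer(subjects)
    idx <- withSeed(seed, sample.int(n))
    nTr <- round(frac * n)
    return(list(train = sort(idx[seq_len(nTr)]),
                test = sort(idx[-seq_len(nTr)])))
  }
  subjects <- as.character(subjects)
  train <- integer(0)
  withSeed(seed, for (s in unique(subjects)) {
    idx <- sample(which(subjects == s))
    train <- c(train, idx[seq_len(round(frac * length(idx)))])
  })
  list(train = sort(train),
       test = sort(setdiff(seq_along(subjects), train)))
}

#' Classification metrics
#'
#' Accuracy plus one-vs-rest sensitivity and specificity, macro-averaged
#' over the classes present in the truth (classes absent from the truth are
#' flagged and excluded from the macro mean).  All values in percent.
#'
#' @param truth,predicted equal-length label vectors.
#' @return list(accuracy, sensitivity, specificity, perClass).
#' @export
classificationMetrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  lev <- sort(unique(c(truth, predicted)))
  per <- lapply(lev, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- sum(truth != cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    data.frame(class = cl, present = (tp + fn) > 0,
               sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA,
               specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA)
  })
  per <- do.call(rbind, per)
  list(accuracy = 100 * mean(truth == predicted),
       sensitivity = mean(per$sensitivity[per$present], na.rm = TRUE),
       specificity = mean(per$specificity[per$present], na.rm = TRUE),
       perClass = per)
}

#' Regression metrics
#'
#' RMSE, MAE and R-squared (1 - SSE/SST); R-squared is NA (flagged with a
#' warning) for zero-variance truth.
#'
#' @param truth,predicted equal-length numeric vectors.
#' @return list(rmse, mae, r2).
#' @export
regressionMetrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 2)
  err <- predicted - truth
  sst <- sum((truth - mean(truth))^2)
  r2 <- if (sst > 0) 1 - sum(err^2) / sst else {
    warning("zero-variance truth: R-squared undefined")
    NA_real_
  }
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)), r2 = r2)
}

## Cross-validate one classifier family over a fold plan.
.cvClassify <- function(x, y, subjects, plan, spec) {
  folds <- plan@folds
  rows <- lapply(seq_along(folds), function(f) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (!length(te)) return(NULL)
    fit <- fitClassifier(x[tr, , drop = FALSE], y[tr], spec)
    m <- classificationMetrics(y[te],
                               predictClassifier(fit, x[te, , drop = FALSE]))
    data.frame(fold = f, accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity)
  })
  out <- do.call(rbind, rows)
  rbind(data.frame(fold = 0, accuracy = mean(out$accuracy),
                   sensitivity = mean(out$sensitivity),
                   specificity = mean(out$specificity)), out)
}

## Cross-validate one regressor family over a fold plan.
.cvRegress <- function(x, y, plan, spec) {
  folds <- plan@folds
  rows <- lapply(seq_along(folds), function(f) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (!length(te)) return(NULL)
    fit <- fitRegressor(x[tr, , drop = FALSE], y[tr], spec)
    m <- regressionMetrics(y[te], predictRegressor(fit, x[te, , drop = FALSE]))
    data.frame(fold = f, rmse = m$rmse, mae = m$mae, r2 = m$r2)
  })
  out <- do.call(rbind, rows)
  rbind(data.frame(fold = 0, rmse = mean(out$rmse), mae = mean(out$mae),
                   r2 = mean(out$r2)), out)
}

## Cross-validate a cascade; reports joint error components.
.cvCascade <- function(x, material, weight, subjects, plan, ordering,
                       cSpec, rSpec) {
  folds <- plan@folds
  rows <- lapply(seq_along(folds), function(f) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    if (!length(te)) return(NULL)
    fit <- cascadeFit(x[tr, , drop = FALSE], material[tr], weight[tr],
                      ordering, cSpec, rSpec)
    pr <- cascadePredict(fit, x[te, , drop = FALSE])
    accM <- 100 * mean(as.character(pr$material) == as.character(material[te]))
    rmseW <- sqrt(mean((pr$weight - weight[te])^2))
    joint <- mean(as.character(pr$material) != as.character(material[te]) |
                    abs(pr$weight - weight[te]) > 1.5)
    data.frame(fold = f, accuracy = accM, rmse = rmseW, jointError = joint)
  })
  out <- do.call(rbind, rows)
  rbind(data.frame(fold = 0, accuracy = mean(out$accuracy),
                   rmse = mean(out$rmse), jointError = mean(out$jointError)),
        out)
}

#' Build a labelled feature table for a cohort
#'
#' Generates the cohort, segments every session (ground-truth slicing by
#' default, or the full detection pipeline), and featurizes the segments.
#'
#' @param nSubjects cohort size.
#' @param protocol an [IngestProtocol-class].
#' @param seed RNG seed.
#' @param segmentation "truth" (slice at the ground-truth events) or
#'   "pipeline" (sync + wrist demarcation + envelope splitting).
#' @param config a [featureConfig()].
#' @return data.frame from [featurizeSegments()].
#' @export
cohortFeatureTable <- function(nSubjects, protocol = IngestProtocol(),
                               seed = 1L, segmentation = c("truth", "pipeline"),
                               config = featureConfig()) {
  segmentation <- match.arg(segmentation)
  seeds <- childSeeds(seed, 2L * nSubjects)
  tabs <- lapply(seq_len(nSubjects), function(i) {
    prof <- sampleSubjectProfile(sprintf("S%02d", i), seeds[i])
    ses <- generateSession(prof, protocol, seed = seeds[nSubjects + i])
    segs <- if (segmentation == "truth") segmentsFromTruth(ses)
            else segmentSession(ses)$segments
    featurizeSegments(segs, config)
  })
  do.call(rbind, tabs)
}

#' Run a full evaluation experiment
#'
#' Generates (or accepts) a cohort feature table and evaluates the requested
#' (task, model, scheme) cells with fivefold cross-validation.  Tasks:
#' `solid-type` (material classification), `solid-weight` (per-material
#' weight regression, reported per class), `sip-volume` (direct volume
#' regression on water segments), `cascade1` (classify-first) and `cascade2`
#' (regress-first).
#'
#' @param config list with elements nSubjects, seed, tasks, schemes,
#'   classifiers (for solid-type), regressor (a [regressorSpec()] family
#'   string for the regression tasks), segmentation.
#' @param features optional pre-computed [cohortFeatureTable()].
#' @return An [EvaluationReport-class].
#' @export
runExperiment <- function(config = list(), features = NULL) {
  cfg <- utils::modifyList(list(
    nSubjects = 20L, seed = 1L,
    tasks = c("solid-type", "solid-weight", "sip-volume", "cascade1",
              "cascade2"),
    schemes = c("AS", "CS"),
    classifiers = c("KNN", "SVM", "DT"),
    regressor = "ET", segmentation = "truth"), config)
  if (is.null(features))
    features <- cohortFeatureTable(cfg$nSubjects, seed = cfg$seed,
                                   segmentation = cfg$segmentation)
  fcols <- featureNames()
  solids <- features[features$label != "water", , drop = FALSE]
  water <- features[features$label == "water", , drop = FALSE]
  out <- NULL
  addRows <- function(out, rows, task, model, scheme) {
    rows$task <- task; rows$model <- model; rows$scheme <- scheme
    if (is.null(out)) rows else merge(out, rows, all = TRUE, sort = FALSE)
  }
  for (scheme in cfg$schemes) {
    planS <- makeFolds(solids$subject, scheme, seed = cfg$seed,
                       classes = solids$label)
    planW <- makeFolds(water$subject, scheme, seed = cfg$seed,
                       classes = water$amount)
    for (task in cfg$tasks) {
      if (task == "solid-type") {
        for (fam in cfg$classifiers) {
          rows <- .cvClassify(solids[, fcols], factor(solids$label),
                              solids$subject, planS,
                              classifierSpec(fam, seed = cfg$seed))
          out <- addRows(out, rows, task, fam, scheme)
        }
      } else if (task == "solid-weight") {
        for (mat in sort(unique(solids$label))) {
          sel <- solids$label == mat
          plan <- makeFolds(solids$subject[sel], scheme, seed = cfg$seed,
                            classes = solids$amount[sel])
          rows <- .cvRegress(solids[sel, fcols], solids$amount[sel], plan,
                             regressorSpec(cfg$regressor, seed = cfg$seed))
          out <- addRows(out, rows, task,
                         paste0(cfg$regressor, ":", mat), scheme)
        }
      } else if (task == "sip-volume") {
        rows <- .cvRegress(water[, fcols], water$amount, planW,
                           regressorSpec(cfg$regressor, seed = cfg$seed))
        out <- addRows(out, rows, task, cfg$regressor, scheme)
      } else if (task %in% c("cascade1", "cascade2")) {
        ordering <- if (task == "cascade1") "classify_first" else
          "regress_first"
        rows <- .cvCascade(solids[, fcols], factor(solids$label),
                           solids$amount, solids$subject, planS, ordering,
                           classifierSpec("DT", seed = cfg$seed),
                           regressorSpec(cfg$regressor, seed = cfg$seed))
        out <- addRows(out, rows, task, paste0("DT+", cfg$regressor), scheme)
      }
    }
  }
  first <- c("task", "model", "scheme", "fold")
  out <- out[, c(first, setdiff(names(out), first))]
  new("EvaluationReport", results = out, config = cfg)
}
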