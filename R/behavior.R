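#' Apply a tag calibration to raw ACC samples
#'
#' Per-axis affine transform to G-force: g = (raw + offset) * scale, the
#' manufacturer/tag-specific calibration contract (e.g. millivolt units with
#' offset -500 and scale 1/1000 map 500 mV to 0 g).
#'
#' @param samples numeric matrix, 3 rows (axes x, y, z) by any number of
#'   sample columns.
#' @param calibration list with numeric 3-vectors `offset` and `scale`
#'   (scale nonzero on all axes).
#' @return calibrated matrix of the same shape (g units).
#' @export
calibrateBurst <- function(samples, calibration) {
  stopifnot(is.matrix(samples), nrow(samples) == 3L)
  if (any(!is.finite(samples))) stop("raw samples must be finite")
  off <- rep_len(calibration$offset, 3L)
  sc <- rep_len(calibration$scale, 3L)
  if (any(sc == 0)) stop("calibration scale must be nonzero on all axes")
  (samples + off) * sc
}

#' Subsample a 10-s burst to the 3-s scheme
#'
#' Devices recording 10 s at 10 Hz (100 samples/axis) are reduced to the
#' common 3-s scheme by retaining the first 30 samples of each axis; bursts
#' already at 30 samples are returned unchanged.
#'
#' @param samples numeric matrix, 3 axes x 30 or 100 samples.
#' @return 3 x 30 matrix.
#' @export
subsampleBurst <- function(samples) {
  stopifnot(is.matrix(samples), nrow(samples) == 3L)
  if (ncol(samples) == 30L) return(samples)
  if (ncol(samples) != 100L)
    stop("expected 30 or 100 samples per axis, got ", ncol(samples))
  samples[, 1:30, drop = FALSE]
}

#' Burst summary features
#'
#' Fixed 19-feature summary of a 3 x 30 burst, in documented order:
#' per-axis mean, sd (sample, n-1 denominator), min, max, range (15
#' features), per-axis mean absolute dynamic component (|sample - per-axis
#' burst mean|, 3 features), and their sum across axes (ODBA-style overall
#' dynamic body acceleration, 1 feature).
#'
#' @param samples numeric 3 x 30 matrix (axes x, y, z).
#' @return named numeric vector of length 19.
#' @export
burstFeatures <- function(samples) {
  stopifnot(is.matrix(samples), nrow(samples) == 3L)
  ax <- c("x", "y", "z")
  mean3 <- rowMeans(samples)
  sd3 <- apply(samples, 1, stats::sd)
  min3 <- apply(samples, 1, min)
  max3 <- apply(samples, 1, max)
  dyn3 <- rowMeans(abs(samples - mean3))
  out <- c(mean3, sd3, min3, max3, max3 - min3, dyn3, sum(dyn3))
  names(out) <- c(paste0("mean_", ax), paste0("sd_", ax), paste0("min_", ax),
                  paste0("max_", ax), paste0("range_", ax), paste0("dyn_", ax),
                  "odba")
  out
}

#' Feature table for a burst data.frame
#'
#' Applies [burstFeatures()] to every row of a burst table with signal
#' columns ax_00..az_29 (as written by [simulateBursts()]), keeping any
#' identifier/label columns.
#'
#' @param bursts burst data.frame.
#' @return data.frame of non-signal columns followed by the 19 features.
#' @export
burstFeatureTable <- function(bursts) {
  sig <- .signalColumns()
  stopifnot(all(sig %in% names(bursts)))
  m <- as.matrix(bursts[, sig])
  feats <- t(apply(m, 1, function(v) burstFeatures(matrix(v, nrow = 3, byrow = TRUE))))
  cbind(bursts[, setdiff(names(bursts), sig), drop = FALSE],
        as.data.frame(feats))
}

#' Label flight by device speed
#'
#' TRUE where device-measured speed is strictly greater than 4.63 km/h (a
#' natural break in the speed density of GPS locations).
#'
#' @param speedKmh nonnegative numeric vector of speeds (km/h).
#' @param threshold speed threshold in km/h (default 4.63).
#' @return logical flight mask.
#' @export
labelFlightBySpeed <- function(speedKmh, threshold = 4.63) {
  if (any(speedKmh < 0, na.rm = TRUE)) stop("speeds must be nonnegative")
  speedKmh > threshold
}

#' Cap a labeled training set per behavior
#'
#' For each behavior with more than `cap` bursts, retains a seeded uniform
#' random subset of size `cap`; behaviors at or under the cap are kept
#' whole (e.g. 118 foraging bursts stay 118 under the default cap of 150).
#'
#' @param bursts labeled data.frame with a `behavior_label` column.
#' @param cap per-behavior maximum (default 150).
#' @param seed integer seed for the subsampling.
#' @return subset of `bursts` (original row order preserved).
#' @export
assembleTrainingSet <- function(bursts, cap = 150L, seed = 1L) {
  stopifnot("behavior_label" %in% names(bursts))
  set.seed(as.integer(seed))
  keep <- logical(nrow(bursts))
  for (b in unique(bursts$behavior_label)) {
    idx <- which(bursts$behavior_label == b)
    if (length(idx) > cap) idx <- sort(sample(idx, cap))
    keep[idx] <- TRUE
  }
  bursts[keep, , drop = FALSE]
}

#' Evaluate a behavior classifier
#'
#' Overall accuracy (proportion of test classifications predicted
#' correctly), per-class precision (probability an assigned behavior was
#' correct: correct assignments of class c over all assignments of c), and
#' per-class recall (probability a true member of c was classified as c).
#' Classes never predicted have undefined (NA) precision.
#'
#' @param predicted,truth equal-length label vectors on the same alphabet.
#' @return a [ClassifierReport-class].
#' @export
evaluateClassifier <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  levs <- sort(unique(c(as.character(predicted), as.character(truth))))
  cm <- table(factor(truth, levels = levs), factor(predicted, levels = levs))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  new("ClassifierReport", accuracy = acc, precision = prec, recall = rec,
      confusion = cm)
}

#' Train a behavior classifier and predict held-out bursts
#'
#' Harness around off-the-shelf supervised learners: splits the feature
#' table into a seeded stratified 80/20 train/test partition, fits the
#' chosen learner on the training part and predicts the held-out part.
#' Learners: random forest ([randomForest::randomForest()], default),
#' support vector machine ([e1071::svm()]), linear discriminant analysis
#' ([MASS::lda()]), or k-nearest neighbors (`class::knn`).
#'
#' @param features data.frame with a `behavior_label` column and numeric
#'   feature columns (e.g. from [burstFeatureTable()]).
#' @param method one of "rf", "svm", "lda", "knn".
#' @param trainFrac training fraction (default 0.8).
#' @param seed integer seed (split and learner randomness).
#' @param ... passed to the learner.
#' @return list: `predicted` and `truth` labels for the held-out part,
#'   `report` (a [ClassifierReport-class]), `testIndex`.
#' @export
trainAndPredict <- function(features, method = c("rf", "svm", "lda", "knn"),
                            trainFrac = 0.8, seed = 1L, ...) {
  method <- match.arg(method)
  stopifnot("behavior_label" %in% names(features))
  y <- factor(features$behavior_label)
  if (nlevels(y) < 2L) stop("training data must contain at least 2 classes")
  x <- features[, setdiff(names(features), "behavior_label"), drop = FALSE]
  x <- x[, vapply(x, is.numeric, TRUE), drop = FALSE]
  if (any(!is.finite(as.matrix(x)))) stop("features must be finite")
  set.seed(as.integer(seed))
  testIdx <- integer()
  for (l in levels(y)) {
    idx <- which(y == l)
    nTest <- max(1L, round((1 - trainFrac) * length(idx)))
    testIdx <- c(testIdx, sample(idx, nTest))
  }
  testIdx <- sort(testIdx)
  trainIdx <- setdiff(seq_along(y), testIdx)
  xtr <- x[trainIdx, , drop = FALSE]; ytr <- droplevels(y[trainIdx])
  xte <- x[testIdx, , drop = FALSE]
  if (nlevels(ytr) < 2L) stop("training split contains a single class")
  pred <- switch(method,
    rf = {
      fit <- randomForest::randomForest(xtr, ytr, ...)
      stats::predict(fit, xte)
    },
    svm = {
      fit <- e1071::svm(xtr, ytr, ...)
      stats::predict(fit, xte)
    },
    lda = {
      fit <- MASS::lda(xtr, grouping = ytr, ...)
      stats::predict(fit, xte)$class
    },
    knn = {
      if (!requireNamespace("class", quietly = TRUE))
        stop("the 'class' package is required for method = 'knn'")
      class::knn(xtr, xte, ytr, ...)
    })
  pred <- as.character(pred)
  truth <- as.character(y[testIdx])
  list(predicted = pred, truth = truth,
       report = evaluateClassifier(pred, truth), testIndex = testIdx)
}
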