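#' Assemble full-curve feature vectors for classification
#'
#' Each sample is represented by the six denaturation curves -- F330, F350,
#' the ratio F350/F330 and their first derivatives -- sampled on the common
#' 35-95 degrees C grid at `gridStep` spacing and concatenated in that fixed
#' block order (default 0.5 degrees C: 121 points x 6 = 726 features).
#' Curves are computed on the full-resolution grid and subsampled, so the
#' derivative estimates do not depend on `gridStep`.
#'
#' @param runs list of [NanoDSFRun-class]; all labelled if labels are to be
#'   used downstream.
#' @param gridStep feature sampling step, degrees C; must be a multiple of
#'   the computation grid step.
#' @param grid computation [TemperatureGrid-class] (default 35-95 at 0.1).
#' @param window,polyorder Savitzky-Golay settings, see [sixCurves()].
#' @return List with `x` (numeric matrix, samples x features, named
#'   `<curve>_<temperature>`), `y` (integer labels, CONTROL = 0, POAG = 1;
#'   NA where unlabelled) and `featureDesc`.
#' @export
assembleFeatures <- function(runs, gridStep = 0.5, grid = TemperatureGrid(),
                             window = 7, polyorder = 3L) {
  stride <- gridStep / grid@step
  if (abs(stride - round(stride)) > 1e-8)
    stop("gridStep must be a multiple of the computation grid step")
  stride <- as.integer(round(stride))
  tt <- gridTemps(grid)
  keep <- seq(1L, length(tt), by = stride)
  blocks <- c("f330", "f350", "ratio", "df330", "df350", "dratio")
  featNames <- as.vector(vapply(blocks, function(b)
    sprintf("%s_%g", b, tt[keep]), character(length(keep))))
  rows <- lapply(runs, function(r) {
    sc <- sixCurves(r, grid, window, polyorder)
    c(sc@f330[keep], sc@f350[keep], sc@ratio[keep],
      sc@dF330[keep], sc@dF350[keep], sc@dRatio[keep])
  })
  x <- do.call(rbind, rows)
  colnames(x) <- featNames
  rownames(x) <- vapply(runs, sampleId, "")
  lab <- vapply(runs, runLabel, "")
  y <- ifelse(lab == "POAG", 1L, ifelse(lab == "CONTROL", 0L, NA_integer_))
  list(x = x, y = as.integer(y),
       featureDesc = sprintf("6 curves x %d points (35-95 degC, step %g degC)",
                             length(keep), gridStep))
}

## The four benchmark learners. Hyperparameters are fixed: LR ridge-penalised
## logistic regression (lambda = 1/n, the C = 1 convention) with up to 1000
## iterations; SVM polynomial kernel of degree 1, cost 1, kernel scale
## 1/n_features; RF 500 trees; AdaBoost 100 rounds over depth-3 trees.
.trainers <- list(
  LR = function(x, y, seed) {
    # ridge-penalised logistic regression at lambda = 1/n (the C = 1
    # convention); fitted along a warm-started path for reliable convergence
    target <- 1 / nrow(x)
    fit <- glmnet::glmnet(x, factor(y, levels = 0:1), family = "binomial",
                          alpha = 0, nlambda = 30L, standardize = FALSE,
                          maxit = 100000L)
    lam <- sort(unique(c(fit$lambda[fit$lambda > target], target)),
                decreasing = TRUE)
    fit <- glmnet::glmnet(x, factor(y, levels = 0:1), family = "binomial",
                          alpha = 0, lambda = lam, standardize = FALSE,
                          maxit = 100000L)
    function(newx)
      as.integer(predict(fit, newx, s = target, type = "class"))
  },
  SVM = function(x, y, seed) {
    fit <- e1071::svm(x, factor(y, levels = 0:1), kernel = "polynomial",
                      degree = 1, coef0 = 0, cost = 1, gamma = 1 / ncol(x),
                      scale = FALSE)
    function(newx)
      as.integer(as.character(predict(fit, newx)))
  },
  RF = function(x, y, seed) {
    fit <- .withSeed(seed, randomForest::randomForest(
      x, factor(y, levels = 0:1), ntree = 500L))
    function(newx)
      as.integer(as.character(predict(fit, newx)))
  },
  ADABOOST = function(x, y, seed) {
    fit <- .adaboostFit(x, y, nRounds = 100L, maxDepth = 3L)
    function(newx) .adaboostPredict(fit, newx)
  })

#' Cross-validated benchmark of the four thermogram classifiers
#'
#' Stratified 5-fold cross-validation of logistic regression (LR), a
#' degree-1 polynomial-kernel SVM (cost 1), a 500-tree random forest (RF)
#' and AdaBoost (100 rounds over depth-3 trees) on full-curve features.
#' Samples are shuffled once under the given seed and dealt into folds
#' class-by-class so every fold preserves the class balance. Per-feature
#' z-scoring is fitted on each training fold only and applied to its test
#' fold (no leakage). Mean accuracy is the average of the fold accuracies;
#' the reported confidence half-width is the normal-approximation 95% CI of
#' that mean, 1.96 SD(folds)/sqrt(k). Pooled out-of-fold predictions give
#' one confusion table per algorithm (positive class = POAG). Results are
#' deterministic for a given seed.
#'
#' @param features list as returned by [assembleFeatures()], or a numeric
#'   matrix (then `labels` must be given).
#' @param labels integer 0/1 vector (CONTROL = 0, POAG = 1); defaults to
#'   `features$y`.
#' @param algorithms subset of c("LR", "SVM", "RF", "ADABOOST").
#' @param nFolds number of folds (default 5).
#' @param seed integer RNG seed for the shuffle and the stochastic learners.
#' @return An [EvaluationReport-class].
#' @export
runCV <- function(features, labels = NULL,
                  algorithms = c("LR", "SVM", "RF", "ADABOOST"),
                  nFolds = 5L, seed = 1L) {
  if (is.list(features) && !is.null(features$x)) {
    x <- features$x
    if (is.null(labels)) labels <- features$y
    featureDesc <- features$featureDesc
  } else {
    x <- as.matrix(features)
    featureDesc <- sprintf("%d features", ncol(x))
  }
  y <- as.integer(labels)
  if (any(is.na(y))) stop("all samples must be labelled")
  if (length(y) != nrow(x)) stop("labels must match rows of the feature matrix")
  if (length(y) < 10L) stop("need at least 10 samples for cross-validation")
  algorithms <- match.arg(algorithms, several.ok = TRUE)

  folds <- .stratifiedFolds(y, nFolds, seed, key = rownames(x))
  for (k in seq_len(nFolds)) {
    if (length(unique(y[folds != k])) < 2L)
      stop("stratification failed: a class is absent from training fold ", k)
  }

  foldRows <- list()
  confusion <- list()
  summaryRows <- list()
  for (alg in algorithms) {
    acc <- numeric(nFolds)
    pooled <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (k in seq_len(nFolds)) {
      tr <- which(folds != k)
      te <- which(folds == k)
      mu <- colMeans(x[tr, , drop = FALSE])
      sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      scale_ <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
      predictor <- .trainers[[alg]](scale_(x[tr, , drop = FALSE]), y[tr],
                                    seed = .childSeed(seed, k))
      pred <- predictor(scale_(x[te, , drop = FALSE]))
      acc[k] <- 100 * mean(pred == y[te])
      pooled <- pooled + c(TP = sum(pred == 1 & y[te] == 1),
                           FP = sum(pred == 1 & y[te] == 0),
                           TN = sum(pred == 0 & y[te] == 0),
                           FN = sum(pred == 0 & y[te] == 1))
    }
    foldRows[[alg]] <- data.frame(algorithm = alg, fold = seq_len(nFolds),
                                  accuracy = acc)
    confusion[[alg]] <- pooled
    summaryRows[[alg]] <- data.frame(
      algorithm = alg, meanAccuracy = mean(acc),
      ciHalfwidth = 1.96 * stats::sd(acc) / sqrt(nFolds))
  }
  new("EvaluationReport",
      folds = do.call(rbind, c(foldRows, make.row.names = FALSE)),
      summary = do.call(rbind, c(summaryRows, make.row.names = FALSE)),
      confusion = confusion, featureDesc = featureDesc,
      seed = as.integer(seed),
      nPerClass = c(CONTROL = sum(y == 0L), POAG = sum(y == 1L)))
}

## Stratified fold assignment: shuffle each class under the seed, deal
## round-robin. When sample keys (ids) are available the within-class order
## is canonicalised by key first, so the same dataset presented in any row
## order lands in identical folds for a given seed.
.stratifiedFolds <- function(y, nFolds, seed, key = NULL) {
  folds <- integer(length(y))
  .withSeed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      if (!is.null(key) && !anyDuplicated(key)) idx <- idx[order(key[idx])]
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

#' Sensitivity and false-positive rate from pooled confusion tables
#'
#' Computes sensitivity TP/(TP + FN) and false-positive rate FP/(FP + TN)
#' as percentages rounded to 0.1, from an [EvaluationReport-class] (one row
#' per algorithm) or from a single named count vector c(TP=, FP=, TN=,
#' FN=). A zero denominator yields NA with an `undefined` flag rather than
#' an error.
#'
#' @param x report or named integer vector.
#' @return data.frame (algorithm, sensitivity, fpr, undefined).
#' @examples
#' confusionRates(c(TP = 57, FP = 23, TN = 148, FN = 25))
#' @export
confusionRates <- function(x) {
  one <- function(alg, cm) {
    sens <- if ((cm[["TP"]] + cm[["FN"]]) == 0) NA_real_
            else round(100 * cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]), 1)
    fpr <- if ((cm[["FP"]] + cm[["TN"]]) == 0) NA_real_
           else round(100 * cm[["FP"]] / (cm[["FP"]] + cm[["TN"]]), 1)
    data.frame(algorithm = alg, sensitivity = sens, fpr = fpr,
               undefined = is.na(sens) || is.na(fpr))
  }
  if (is(x, "EvaluationReport")) {
    out <- do.call(rbind, lapply(names(x@confusion), function(a)
      one(a, x@confusion[[a]])))
  } else {
    out <- one("pooled", x)
  }
  rownames(out) <- NULL
  out
}
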