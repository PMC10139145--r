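sepFeatures <- function(n = 15L, gridStep = 2.0, seed = 5L) {
  ds <- generateCohort(smallSeparatedConfig(n = n, seed = seed))
  assembleFeatures(cohortRuns(ds), gridStep = gridStep)
}

test_that("feature assembly has the documented grid arithmetic and order", {
  ds <- generateCohort(CohortConfig(n = c(CONTROL = 5L, POAG = 5L), seed = 2L))
  f <- assembleFeatures(cohortRuns(ds), gridStep = 0.5)
  expect_equal(dim(f$x), c(10L, 726L))
  expect_equal(dim(assembleFeatures(cohortRuns(ds), gridStep = 1.0)$x),
               c(10L, 366L))
  one <- assembleFeatures(cohortRuns(ds)[1], gridStep = 0.5)
  expect_equal(dim(one$x), c(1L, 726L))
  expect_equal(colnames(f$x)[1], "f330_35")
  expect_equal(colnames(f$x)[122], "f350_35")
  expect_true(all(grepl("^dratio_", colnames(f$x)[606:726])))
  expect_equal(f$y, rep(0:1, each = 5L))
  expect_error(assembleFeatures(cohortRuns(ds), gridStep = 0.33),
               "multiple")
})

test_that("all four learners separate a well-separated cohort", {
  rep <- runCV(sepFeatures(), seed = 3L)
  s <- accuracySummary(rep)
  expect_setequal(s$algorithm, c("LR", "SVM", "RF", "ADABOOST"))
  expect_true(all(s$meanAccuracy >= 95))
  expect_true(all(s$ciHalfwidth >= 0))
  cm <- pooledConfusion(rep)[["LR"]]
  expect_equal(sum(cm), 30)
})

test_that("permuted labels give chance-level accuracy within the binomial band", {
  f <- sepFeatures()
  n <- length(f$y)
  band <- 100 * 1.96 * sqrt(0.25 / n)
  set.seed(13)
  yp <- sample(f$y)
  s <- accuracySummary(runCV(f$x, labels = yp, seed = 3L))
  expect_true(all(abs(s$meanAccuracy - 50) <= band))
})

test_that("chance-level behaviour persists across seeded permutation repeats", {
  # Across 20 seeded permutations, every learner must stay at chance on
  # average: per-repetition CV accuracy is overdispersed relative to a
  # binomial count (training folds overlap), so the stable leakage check is
  # that each learner's mean over repetitions lies well inside the
  # single-repetition binomial band. A scaling or fold leak would push the
  # means far above it.
  f <- sepFeatures(n = 25L)
  n <- length(f$y)
  band <- 100 * 1.96 * sqrt(0.25 / n)
  acc <- matrix(NA_real_, 20, 4)
  for (r in 1:20) {
    set.seed(100 + r)
    yp <- sample(f$y)
    s <- accuracySummary(runCV(f$x, labels = yp, seed = r))
    acc[r, ] <- s$meanAccuracy
  }
  expect_true(all(abs(colMeans(acc) - 50) <= band))
  expect_true(all(acc >= 20 & acc <= 80))   # no repetition near separation
})

test_that("full-dataset scaling does not change the permutation-null conclusion", {
  f <- sepFeatures()
  n <- length(f$y)
  band <- 100 * 1.96 * sqrt(0.25 / n)
  set.seed(13)
  yp <- sample(f$y)
  xs <- scale(f$x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  rownames(xs) <- rownames(f$x)
  s <- accuracySummary(runCV(xs, labels = yp, seed = 3L))
  expect_true(all(abs(s$meanAccuracy - 50) <= band))
})

test_that("reports are bit-reproducible and order-invariant under a fixed seed", {
  f <- sepFeatures()
  a <- runCV(f, seed = 7L)
  b <- runCV(f, seed = 7L)
  expect_identical(foldAccuracies(a), foldAccuracies(b))
  expect_identical(pooledConfusion(a), pooledConfusion(b))
  perm <- sample(nrow(f$x))
  c <- runCV(f$x[perm, ], labels = f$y[perm], seed = 7L)
  expect_equal(foldAccuracies(c)$accuracy, foldAccuracies(a)$accuracy)
})

test_that("the evaluation report summarises folds with a normal 95% CI", {
  f <- sepFeatures()
  rep <- runCV(f, algorithms = "LR", seed = 1L)
  folds <- foldAccuracies(rep)
  expect_equal(nrow(folds), 5L)
  s <- accuracySummary(rep)
  expect_equal(s$meanAccuracy, mean(folds$accuracy))
  expect_equal(s$ciHalfwidth, 1.96 * sd(folds$accuracy) / sqrt(5))
})

test_that("confusion rates follow the stated arithmetic", {
  # constructed table: 57/25 positives split, 23/148 negatives split
  r <- confusionRates(c(TP = 57, FP = 23, TN = 148, FN = 25))
  expect_equal(r$sensitivity, 69.5)
  expect_equal(r$fpr, 13.5)
  expect_false(r$undefined)
  perfect <- confusionRates(c(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(c(perfect$sensitivity, perfect$fpr), c(100, 0))
  allneg <- confusionRates(c(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_equal(c(allneg$sensitivity, allneg$fpr), c(0, 0))
  undef <- confusionRates(c(TP = 0, FP = 2, TN = 8, FN = 0))
  expect_true(undef$undefined)
  expect_true(is.na(undef$sensitivity))
})

test_that("cross-validation rejects unusable inputs", {
  f <- sepFeatures(n = 6L)
  expect_error(runCV(f$x[1:8, ], labels = f$y[1:8]), "at least 10")
  expect_error(runCV(f$x, labels = rep(NA_integer_, nrow(f$x))), "labelled")
})
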