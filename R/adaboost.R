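## AdaBoost.M1 (discrete, two-class) over depth-limited CART weak learners.
## Weak learners are rpart trees grown without pruning (cp = 0) at the given
## maximum depth, fitted to the current case weights; classic exponential
## reweighting with learner weight alpha = 0.5 log((1 - err)/err).
.adaboostFit <- function(x, y, nRounds = 100L, maxDepth = 3L) {
  y <- as.integer(y)                    # 0/1
  stopifnot(all(y %in% c(0L, 1L)))
  ypm <- ifelse(y == 1L, 1, -1)
  n <- length(y)
  df <- data.frame(.y = factor(y, levels = c(0L, 1L)), x)
  ctrl <- rpart::rpart.control(maxdepth = maxDepth, minsplit = 2,
                               minbucket = 1, cp = 0, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(nRounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    predpm <- ifelse(pred == 1L, 1, -1)
    err <- sum(w[predpm != ypm])
    if (err >= 0.5) break               # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break             # perfect learner: margin saturated
    w <- w * exp(-alpha * ypm * predpm)
    w <- w / sum(w)
  }
  if (!length(trees)) {
    # no usable weak learner: predict the weighted majority class
    structure(list(majority = as.integer(sum(w[y == 1L]) >= 0.5)),
              class = "tfdpAdaboost")
  } else {
    structure(list(trees = trees, alphas = alphas), class = "tfdpAdaboost")
  }
}

.adaboostPredict <- function(model, x) {
  if (!is.null(model$majority))
    return(rep(model$majority, nrow(x)))
  df <- as.data.frame(x)
  score <- numeric(nrow(df))
  for (m in seq_along(model$trees)) {
    pred <- as.integer(as.character(
      predict(model$trees[[m]], df, type = "class")))
    score <- score + model$alphas[m] * ifelse(pred == 1L, 1, -1)
  }
  as.integer(score > 0)
}
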