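#' AdaBoost over decision trees (SAMME)
#'
#' Discrete AdaBoost with depth-limited CART trees as weak learners.
#' Boosting is fully deterministic given the data and hyperparameters:
#' each round fits a weighted tree to the current example weights, so
#' repeated fits under different seeds give bitwise-identical models -
#' the mechanism behind the zero-SD stability of this family.
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 labels.
#' @param n_estimators Boosting rounds (default 50).
#' @param maxdepth Weak-learner depth (default 1, stumps).
#' @param learning_rate Shrinkage on the stage weights (default 1).
#' @return An `adaboost` fit (list of trees and stage weights).
#' @export
adaboostFit <- function(x, y, n_estimators = 50L, maxdepth = 1L,
                        learning_rate = 1) {
  y2 <- ifelse(y == 1L, 1, -1)
  n <- length(y2)
  w <- rep(1 / n, n)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("X", seq_len(ncol(x)))
  df <- data.frame(.y = factor(y, levels = c(0, 1)), x)
  trees <- list(); alphas <- numeric()
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- ifelse(stats::predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != y2])
    if (err >= 0.5 || err <= 0) {
      if (err <= 0) { trees[[m]] <- fit; alphas[m] <- 1 }
      break
    }
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    trees[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(-alpha * y2 * pred)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, colnames = colnames(x)),
            class = "adaboost")
}

#' @rdname adaboostFit
#' @param fit An `adaboost` fit.
#' @return `adaboostScore` returns class-1 scores in `[0, 1]` (the signed
#'   vote margin mapped affinely onto the unit interval).
#' @export
adaboostScore <- function(fit, x) {
  if (is.null(colnames(x)))
    colnames(x) <- paste0("X", seq_len(ncol(x)))
  df <- data.frame(x)
  if (!length(fit$trees) || sum(abs(fit$alphas)) == 0)
    return(rep(0.5, nrow(df)))
  margin <- rep(0, nrow(df))
  for (m in seq_along(fit$trees)) {
    pred <- ifelse(stats::predict(fit$trees[[m]], df, type = "class") == "1",
                   1, -1)
    margin <- margin + fit$alphas[m] * pred
  }
  (margin / sum(abs(fit$alphas)) + 1) / 2
}
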