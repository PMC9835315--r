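#' Model families
#'
#' The eleven supported classifier families: nine classical families and
#' the two attention networks.
#'
#' @return Character vector of family codes.
#' @export
modelFamilies <- function() {
  c("SVC", "RF", "KNN", "DT", "GBDT", "ABDT", "GNB", "SGD", "LR",
    "FusionNet", "SmilesNet")
}

#' Train a classical classifier
#'
#' One train contract for the nine classical families; every fitted model
#' exposes a class-1 score in `[0, 1]` via [predictScores()] and a label
#' via [predictLabels()] at the fixed 0.5 operating point.
#'
#' @param family One of `"SVC"`, `"RF"`, `"KNN"`, `"DT"`, `"GBDT"`,
#'   `"ABDT"`, `"GNB"`, `"SGD"`, `"LR"`.
#' @param x Numeric feature matrix.
#' @param y 0/1 labels (both classes must be present).
#' @param hyper Named list of hyperparameters (family-specific; see the
#'   shipped search spaces for the recognised names).
#' @param seed Integer seed (consumed by the stochastic families).
#' @return A `ChemFusionModel` (list with `family`, `hyper`, `fit`).
#' @export
trainClassifier <- function(family, x, y, hyper = list(), seed = 1L) {
  family <- match.arg(family, setdiff(modelFamilies(), c("FusionNet", "SmilesNet")))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  x <- as.matrix(x)
  fit <- withSeed(seed, switch(family,
    SVC = {
      h <- modifyList(list(cost = 1, gamma = 1 / ncol(x), kernel = "radial"), hyper)
      e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE,
                 cost = h$cost, gamma = h$gamma, kernel = h$kernel,
                 scale = FALSE)
    },
    RF = {
      h <- modifyList(list(ntree = 500,
                           mtry = max(1, floor(sqrt(ncol(x))))), hyper)
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = h$ntree, mtry = min(h$mtry, ncol(x)))
    },
    KNN = {
      h <- modifyList(list(k = 5L), hyper)
      if (h$k > nrow(x)) stop("KNN k exceeds the number of training rows")
      list(train = x, y = y, k = h$k)
    },
    DT = {
      h <- modifyList(list(maxdepth = 10L, cp = 0.01, minsplit = 20L), hyper)
      df <- data.frame(.y = factor(y, levels = c(0, 1)), x)
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(maxdepth = h$maxdepth,
                                                  cp = h$cp,
                                                  minsplit = h$minsplit))
    },
    GBDT = {
      h <- modifyList(list(nrounds = 100L, max_depth = 3L, eta = 0.1,
                           subsample = 1), hyper)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = h$max_depth, eta = h$eta,
                      subsample = h$subsample, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = h$nrounds, verbose = 0)
    },
    ABDT = {
      h <- modifyList(list(n_estimators = 50L, maxdepth = 1L,
                           learning_rate = 1), hyper)
      adaboostFit(x, y, n_estimators = h$n_estimators,
                  maxdepth = h$maxdepth, learning_rate = h$learning_rate)
    },
    GNB = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    SGD = {
      h <- modifyList(list(lambda = 1e-4, epochs = 20L, eta0 = 0.01,
                           loss = "log"), hyper)
      sgdFit(x, y, lambda = h$lambda, epochs = h$epochs, eta0 = h$eta0,
             loss = h$loss, seed = seed)
    },
    LR = {
      # ridge-penalised logistic fit (C = 1 in sklearn terms); the
      # quasi-Newton solver is deterministic, so refits under different
      # seeds are identical
      h <- modifyList(list(C = 1), hyper)
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = 1 / (h$C * length(y)), standardize = FALSE)
    }))
  structure(list(family = family, hyper = hyper, fit = fit, seed = seed),
            class = "ChemFusionModel")
}

#' Predict class-1 scores
#'
#' @param model A fitted `ChemFusionModel` (classical) or network
#'   predictor.
#' @param x Feature matrix (or token list for `SmilesNet`).
#' @return Numeric scores in `[0, 1]`.
#' @export
predictScores <- function(model, x) {
  UseMethod("predictScores")
}

#' @export
predictScores.ChemFusionModel <- function(model, x) {
  x <- as.matrix(x)
  s <- switch(model$family,
    SVC = {
      p <- stats::predict(model$fit, x, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    },
    RF = stats::predict(model$fit, x, type = "prob")[, "1"],
    KNN = {
      pred <- class::knn(model$fit$train, x,
                         factor(model$fit$y, levels = c(0, 1)),
                         k = model$fit$k, prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "1", pwin, 1 - pwin)
    },
    DT = stats::predict(model$fit, data.frame(x), type = "prob")[, "1"],
    GBDT = stats::predict(model$fit, x),
    ABDT = adaboostScore(model$fit, x),
    GNB = stats::predict(model$fit, x, type = "raw")[, "1"],
    SGD = sgdScore(model$fit, x),
    LR = as.numeric(stats::predict(model$fit, x, type = "response")))
  s <- as.numeric(s)
  stopifnot(all(is.finite(s)))
  pmin(1, pmax(0, s))
}

#' Predict labels at the 0.5 operating point
#'
#' @inheritParams predictScores
#' @return Integer 0/1 labels, 1 iff score >= 0.5.
#' @export
predictLabels <- function(model, x) {
  as.integer(predictScores(model, x) >= 0.5)
}

#' Shipped randomized-search spaces
#'
#' Default hyperparameter distributions per classical family, read from
#' the packaged `extdata/search_spaces.yaml` (overridable by supplying
#' your own file).
#'
#' @param path Optional path to a YAML file in the same layout.
#' @return Named list of per-family search spaces.
#' @export
searchSpaces <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "search_spaces.yaml", package = "ChemFusion")
  yaml::read_yaml(path)
}

# Sample one configuration from a search-space description.
.sample_config <- function(space) {
  cfg <- lapply(space, function(par) {
    if (!is.null(par$values)) {
      v <- par$values[[sample.int(length(par$values), 1L)]]
      v
    } else if (isTRUE(par$log)) {
      exp(stats::runif(1, log(par$min), log(par$max)))
    } else if (isTRUE(par$integer)) {
      sample(seq(par$min, par$max), 1L)
    } else {
      stats::runif(1, par$min, par$max)
    }
  })
  cfg
}

#' Randomized hyperparameter search with cross-validated AUC
#'
#' Samples `n_iter` configurations from the family's search space and
#' scores each by `n_folds`-fold cross-validated AUC on the supplied
#' (train + validation) data; the best configuration is returned with the
#' full trial log. A configuration that fails on a fold (e.g. a
#' degenerate k for KNN) scores `-Inf` and cannot win.
#'
#' @param family Classical family code.
#' @param x,y Training features and 0/1 labels.
#' @param space Search space (default: the family's entry in
#'   [searchSpaces()]); a family without a space trains with defaults and
#'   a warning.
#' @param n_iter Configurations to sample (default 10).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed (sampling, folds, and model fits).
#' @return List with `best` (hyperparameter list), `cv_auc`, `trials`
#'   (data.frame log).
#' @export
randomizedSearch <- function(family, x, y, space = searchSpaces()[[family]],
                             n_iter = 10L, n_folds = 5L, seed = 1L) {
  if (is.null(space) || !length(space)) {
    warning("no search space for family ", family, "; using defaults")
    return(list(best = list(), cv_auc = NA_real_,
                trials = data.frame()))
  }
  y <- as.integer(y)
  seeds <- deriveSeeds(seed, n_iter + 1L)
  folds <- withSeed(seeds[1], sample(rep_len(seq_len(n_folds), length(y))))
  configs <- withSeed(seed, replicate(n_iter, .sample_config(space),
                                      simplify = FALSE))
  scores <- vapply(seq_len(n_iter), function(i) {
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
        return(NA_real_)
      m <- tryCatch(trainClassifier(family, x[tr, , drop = FALSE], y[tr],
                                    configs[[i]], seed = seeds[i + 1L]),
                    error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      s <- tryCatch(predictScores(m, x[!tr, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(s)) return(-Inf)
      computeMetrics(as.integer(s >= 0.5), s, y[!tr])[["auc"]]
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  best_i <- which.max(scores)
  trials <- data.frame(iter = seq_len(n_iter), cv_auc = scores,
                       config = vapply(configs, function(cfg)
                         paste(names(cfg), unlist(cfg), sep = "=",
                               collapse = ";"), ""))
  list(best = configs[[best_i]], cv_auc = scores[best_i], trials = trials)
}
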