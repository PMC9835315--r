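# A linearly separable 2-D toy problem used across the family checks.
toy_sep <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n, -2, 0.4), ncol = 2),
               matrix(rnorm(n, 2, 0.4), ncol = 2))
    list(x = x, y = rep(c(0L, 1L), each = n / 2))
  })
}

test_that("every classical family honours the score/label contract", {
  toy <- toy_sep()
  for (fam in c("SVC", "RF", "KNN", "DT", "GBDT", "ABDT", "GNB", "SGD", "LR")) {
    m <- trainClassifier(fam, toy$x, toy$y, seed = 2)
    s <- predictScores(m, toy$x)
    expect_true(all(is.finite(s)) && all(s >= 0) && all(s <= 1),
                info = fam)
    expect_equal(predictLabels(m, toy$x), as.integer(s >= 0.5), info = fam)
  }
})

test_that("trees separate a separable toy set perfectly", {
  toy <- toy_sep()
  for (fam in c("DT", "RF")) {
    m <- trainClassifier(fam, toy$x, toy$y, seed = 3)
    expect_equal(mean(predictLabels(m, toy$x) == toy$y), 1, info = fam)
  }
})

test_that("single-class training labels are rejected", {
  toy <- toy_sep()
  expect_error(trainClassifier("RF", toy$x, rep(1L, nrow(toy$x))),
               "single class")
})

test_that("label flipping mirrors the AUC for score-symmetric families", {
  toy <- toy_sep(n = 80, seed = 5)
  noisy <- toy
  noisy$x <- noisy$x + matrix(rnorm(length(noisy$x), 0, 1.5),
                              nrow(noisy$x))
  for (fam in c("GNB", "LR")) {
    m1 <- trainClassifier(fam, noisy$x, noisy$y, seed = 1)
    m2 <- trainClassifier(fam, noisy$x, 1L - noisy$y, seed = 1)
    auc1 <- computeMetrics(predictLabels(m1, noisy$x),
                           predictScores(m1, noisy$x), noisy$y)[["auc"]]
    auc2 <- computeMetrics(predictLabels(m2, noisy$x),
                           predictScores(m2, noisy$x), noisy$y)[["auc"]]
    expect_equal(auc2, 1 - auc1, tolerance = 1e-6, info = fam)
  }
})

test_that("deterministic families give identical refits across seeds", {
  cs <- fx_small()
  md <- makeModelData(cs, 3)
  trval <- md$partition %in% c("train", "validation")
  x <- md$x[trval, , drop = FALSE]; y <- md$y[trval]
  xt <- md$x[md$partition == "test", , drop = FALSE]
  for (fam in c("ABDT", "GNB", "LR")) {
    s1 <- predictScores(trainClassifier(fam, x, y, seed = 101), xt)
    s2 <- predictScores(trainClassifier(fam, x, y, seed = 202), xt)
    expect_identical(s1, s2, info = fam)
  }
})

test_that("randomized search is seeded, logged, and skips degenerate configs", {
  toy <- toy_sep(n = 40, seed = 7)
  # singleton space returns that configuration
  single <- list(k = list(values = list(3L)))
  r <- randomizedSearch("KNN", toy$x, toy$y, space = single,
                        n_iter = 3L, n_folds = 3L, seed = 1)
  expect_equal(r$best$k, 3L)
  # same seed twice: identical winner and trial log
  sp <- searchSpaces()[["RF"]]
  r1 <- randomizedSearch("RF", toy$x, toy$y, space = sp, n_iter = 4L,
                         n_folds = 3L, seed = 9)
  r2 <- randomizedSearch("RF", toy$x, toy$y, space = sp, n_iter = 4L,
                         n_folds = 3L, seed = 9)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$trials, r2$trials)
  expect_equal(nrow(r1$trials), 4L)
  # a degenerate configuration (k > n) cannot win over a valid one
  both <- list(k = list(values = list(5L, 1000L)))
  rb <- randomizedSearch("KNN", toy$x, toy$y, space = both,
                         n_iter = 6L, n_folds = 4L, seed = 2)
  expect_equal(rb$best$k, 5L)
  # family without a space falls back to defaults with a warning
  expect_warning(r0 <- randomizedSearch("GNB", toy$x, toy$y,
                                        space = list(), seed = 1),
                 "defaults")
  expect_equal(r0$best, list())
})

test_that("hinge-loss SGD calibrates margins onto the unit interval", {
  toy <- toy_sep(n = 50, seed = 3)
  m <- trainClassifier("SGD", toy$x, toy$y,
                       hyper = list(loss = "hinge"), seed = 1)
  s <- predictScores(m, toy$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(computeMetrics(as.integer(s >= .5), s, toy$y)[["auc"]], 0.95)
})
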