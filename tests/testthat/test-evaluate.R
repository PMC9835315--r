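test_that("metrics match their defining formulas", {
  truth <- c(1, 1, 1, 0, 0, 0)
  perfect <- computeMetrics(truth, truth, truth)
  expect_equal(unname(perfect), c(1, 1, 1))
  # TP=2 FP=1 FN=1 TN=2
  pred <- c(1, 1, 0, 1, 0, 0)
  m <- computeMetrics(pred, pred, truth)
  expect_equal(m[["acc"]], 4 / 6)
  expect_equal(m[["f1"]], 2 * 2 / (2 * 2 + 1 + 1))
  # fully tied scores give AUC 0.5 under midrank correction
  tied <- computeMetrics(rep(0, 6), rep(0.3, 6), truth)
  expect_equal(tied[["auc"]], 0.5)
  expect_warning(computeMetrics(c(1, 1), c(.9, .8), c(1, 1)), "single class")
  expect_error(computeMetrics(c(1), c(.9, .8), c(1, 0)))
})

test_that("the Welch test handles degenerate zero-variance vectors", {
  a <- c(0.9, 0.9, 0.9)
  r <- pairwiseTTest(a, a)
  expect_equal(r$t, 0); expect_equal(r$p, 1); expect_false(r$significant)
  r2 <- pairwiseTTest(a, c(0.8, 0.8, 0.8))
  expect_true(r2$significant)
  expect_true(r2$degenerate)
  # sign flips under argument swap, p unchanged
  set.seed(1)
  x <- rnorm(20, 0.85, 0.02); z <- rnorm(20, 0.80, 0.03)
  r3 <- pairwiseTTest(x, z); r4 <- pairwiseTTest(z, x)
  expect_equal(r3$t, -r4$t)
  expect_equal(r3$p, r4$p)
})

test_that("well-separated seed distributions are overwhelmingly significant", {
  set.seed(42)
  a <- rnorm(30, 0.9, 0.01)
  b <- rnorm(30, 0.8, 0.01)
  expect_lt(pairwiseTTest(a, b)$p, 1e-6)
})

test_that("seed aggregation reports mean and SD under both conventions", {
  runs <- c(0.8, 0.9)
  s <- repeatOverSeeds(function(seed) c(metric = runs[seed]), seeds = 1:2)
  expect_equal(unname(s$mean["metric"]), 0.85)
  expect_equal(unname(s$sd["metric"]), 0.05)  # population SD
  s2 <- repeatOverSeeds(function(seed) c(metric = runs[seed]), seeds = 1:2,
                        sd_type = "sample")
  expect_equal(unname(s2$sd["metric"]), sd(runs))
  expect_equal(unname(round(s2$sd["metric"], 4)), 0.0707)
  const <- repeatOverSeeds(function(seed) c(m = 0.42), seeds = 1:5)
  expect_equal(unname(const$mean["m"]), 0.42)
  expect_equal(unname(const$sd["m"]), 0)
  # a failing seed marks the summary incomplete but keeps the rest
  part <- repeatOverSeeds(function(seed) {
    if (seed == 3) stop("boom") else c(m = seed)
  }, seeds = 1:4)
  expect_false(part$complete)
  expect_equal(part$n_seeds, 3L)
  expect_match(part$failures[["3"]], "boom")
  # aggregation round-trips from the retained per-seed rows
  expect_equal(mean(part$per_seed$m), unname(part$mean["m"]))
})

test_that("prediction overlap partitions the test set exactly", {
  truth <- c(1, 0, 1, 0)
  same <- predictionOverlap(truth, truth, truth)
  expect_equal(unname(same$counts),  c(4, 0, 0, 0))
  expect_equal(unname(same$overlap_correct), 100)
  comp <- predictionOverlap(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(unname(comp$counts), c(0, 2, 0, 0))
  # A correct on {1,2,3}, B correct on {2,3,4}
  tr <- c(1, 1, 1, 1)
  a <- c(1, 1, 1, 0); b <- c(0, 1, 1, 1)
  o <- predictionOverlap(a, b, tr)
  expect_equal(unname(o$counts), c(2, 1, 1, 0))
  expect_equal(sum(o$counts), 4L)
  expect_error(predictionOverlap(c(1, 0), c(1, 0, 1), c(1, 0)))
})

test_that("t-SNE maps have the right shape, determinism and separation", {
  set.seed(2)
  x <- rbind(matrix(rnorm(15 * 4, 0), ncol = 4),
             matrix(rnorm(15 * 4, 8), ncol = 4))
  lab <- rep(0:1, each = 15)
  y1 <- tsneEmbed(x, seed = 5, n_iter = 500L, perplexity = 8)
  y2 <- tsneEmbed(x, seed = 5, n_iter = 500L, perplexity = 8)
  expect_equal(dim(y1), c(30L, 2L))
  expect_identical(y1, y2)
  c0 <- colMeans(y1[lab == 0, ]); c1 <- colMeans(y1[lab == 1, ])
  spread <- mean(c(sqrt(rowSums(sweep(y1[lab == 0, ], 2, c0)^2)),
                   sqrt(rowSums(sweep(y1[lab == 1, ], 2, c1)^2))))
  expect_gt(sqrt(sum((c0 - c1)^2)), spread)
})

test_that("chemical-space maps are produced per modality", {
  cs <- fx_small()[1:120]
  maps <- suppressMessages(chemspaceMap(cs, c("maccs", "ecfp4"), seed = 3,
                                        n_iter = 120L))
  expect_named(maps, c("maccs", "ecfp4"))
  expect_equal(dim(maps$maccs), c(120L, 2L))
  expect_error(chemspaceMap(fx_small()[1:5]), "at least 10")
})
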