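test_that("attention weights are a proper row-stochastic matrix", {
  set.seed(1)
  inp <- matrix(rnorm(5 * 6), 5, 6)
  Wq <- matrix(rnorm(24), 6); Wk <- matrix(rnorm(24), 6)
  Wv <- matrix(rnorm(36), 6)
  at <- selfAttention(inp, Wq, Wk, Wv)
  expect_equal(rowSums(at$weights), rep(1, 5))
  expect_equal(dim(at$output), c(5L, 6L))
  # length-1 sequence: weight 1, output equals the value projection
  at1 <- selfAttention(inp[1, , drop = FALSE], Wq, Wk, Wv)
  expect_equal(at1$weights[1, 1], 1)
  expect_equal(at1$output, inp[1, , drop = FALSE] %*% Wv)
  # identical inputs at all positions attend to their common mean
  same <- inp[rep(2, 4), ]
  ats <- selfAttention(same, Wq, Wk, Wv)
  expect_lt(max(abs(sweep(ats$output, 2, ats$output[1, ]))), 1e-12)
  # masked positions receive zero weight
  atm <- selfAttention(inp, Wq, Wk, Wv, mask = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(atm$weights[, 4:5]), matrix(0, 5, 2))
})

test_that("analytic network gradients match finite differences", {
  # fusion network
  net <- buildFusionNet(attentionConfig(proj_dim = 5L, att_dim = 4L),
                        n_blocks = 2, input_dim = 6, seed = 11)
  set.seed(3)
  x <- matrix(rnorm(8 * 12), 8, 12); y <- rep(c(0, 1), 4)
  fwd <- ChemFusion:::.fusion_forward(net, x, keep_cache = TRUE)
  g <- ChemFusion:::.fusion_backward(net, fwd$cache,
                                     ChemFusion:::.bce(fwd$z, y)$dz)
  loss_at <- function(net) ChemFusion:::.bce(
    ChemFusion:::.fusion_forward(net, x)$z, y)$loss
  for (k in names(net$params)) {
    i <- sample(length(net$params[[k]]), 1L)
    eps <- 1e-5
    n1 <- net; n1$params[[k]][i] <- n1$params[[k]][i] + eps
    n2 <- net; n2$params[[k]][i] <- n2$params[[k]][i] - eps
    num <- (loss_at(n1) - loss_at(n2)) / (2 * eps)
    expect_equal(g[[k]][i], num, tolerance = 1e-4, info = k)
  }
  # SMILES network
  vocab <- setNames(0:5, c("<pad>", "A", "B", "C", "D", "E"))
  snet <- buildSmilesNet(attentionConfig(lstm_hidden = 4L, att_dim = 3L),
                         vocab, seed = 11)
  X <- matrix(c(1, 2, 3, 0, 0, 2, 2, 4, 5, 1, 5, 4, 3, 2, 1, 1, 1, 0, 0, 0),
              4, 5, byrow = TRUE)
  lens <- c(3L, 5L, 5L, 2L); ys <- c(0, 1, 1, 0)
  sf <- ChemFusion:::.smilesnet_forward(snet, X, lens, keep_cache = TRUE)
  sg <- ChemFusion:::.smilesnet_backward(snet, sf$cache,
                                         ChemFusion:::.bce(sf$z, ys)$dz)
  sloss <- function(net) ChemFusion:::.bce(
    ChemFusion:::.smilesnet_forward(net, X, lens)$z, ys)$loss
  for (k in c("E", "W1", "U2", "b3", "W4", "Wq", "Wk", "Wv", "headW")) {
    p <- snet$params[[k]]
    i <- if (k == "E") 2L + nrow(p) else sample(length(p), 1L)  # skip pad row
    eps <- 1e-5
    n1 <- snet; n1$params[[k]][i] <- n1$params[[k]][i] + eps
    n2 <- snet; n2$params[[k]][i] <- n2$params[[k]][i] - eps
    num <- (sloss(n1) - sloss(n2)) / (2 * eps)
    expect_equal(sg[[k]][i], num, tolerance = 1e-3, info = k)
  }
})

test_that("the fusion network respects its stacking and output contracts", {
  net <- buildFusionNet(attentionConfig(), n_blocks = 3, seed = 2)
  # four fully connected layers in total: three projections plus the head
  expect_length(grep("^projW", names(net$params)), 3L)
  expect_length(grep("^extraW", names(net$params)), 0L)
  net1 <- buildFusionNet(attentionConfig(), n_blocks = 1, seed = 2)
  expect_length(grep("^extraW", names(net1$params)), 2L)
  set.seed(6)
  x <- matrix(rnorm(1000 * 384), 1000)
  f <- ChemFusion:::.fusion_forward(net, x, keep_cache = TRUE)
  expect_length(f$score, 1000L)
  expect_true(all(f$score > 0 & f$score < 1))
  # attention input is the (n_blocks, proj_dim) stack
  expect_length(f$cache$H, 3L)
  expect_equal(dim(f$cache$H[[1]]), c(1000L, 64L))
  # untrained scores hover near 0.5 under symmetric initialization
  expect_gt(mean(f$score), 0.4)
  expect_lt(mean(f$score), 0.6)
})

test_that("the SMILES network embeds at width 100 and rejects bad input", {
  vocab <- buildVocabulary(c("CCO", "c1ccccc1"))
  net <- buildSmilesNet(attentionConfig(lstm_hidden = 8L), vocab, seed = 1)
  expect_equal(ncol(net$params$E), 100L)
  expect_equal(net$params$E[1, ], rep(0, 100))  # pad row is the zero vector
  expect_error(attentionConfig(embedding_dim = 64L), "fixed")
  expect_error(attentionConfig(lstm_layers = 2L), "fixed")
  enc <- encodeSmiles(c("CCO", "c1ccccc1"), vocab, max_len = 12L)
  s <- predictScores(net, enc)
  expect_length(s, 2L)
  expect_true(all(s > 0 & s < 1))
  # all-pad input errors
  expect_error(ChemFusion:::.smilesnet_forward(net, matrix(0L, 1, 5), 0L),
               "all-pad")
  # token ids beyond the vocabulary error
  bad <- enc; bad$sequences[1, 1] <- 99L
  expect_error(predictScores(net, bad))
})

test_that("seeded training is reproducible and sensitive to the seed", {
  set.seed(8)
  x <- matrix(rnorm(120 * 8), 120)
  y <- as.integer(x[, 1] + 0.3 * rnorm(120) > 0)
  cfg <- attentionConfig(proj_dim = 8L, att_dim = 4L, max_epochs = 5L,
                         batch_size = 32L)
  net0 <- buildFusionNet(cfg, n_blocks = 1, input_dim = 8, seed = 4)
  t1 <- trainNetwork(net0, x[1:90, ], y[1:90], x[91:120, ], y[91:120],
                     seed = 6)
  t2 <- trainNetwork(net0, x[1:90, ], y[1:90], x[91:120, ], y[91:120],
                     seed = 6)
  expect_identical(t1$params, t2$params)
  expect_equal(t1$log, t2$log)
  expect_true(t1$trained)
})
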