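#' Build the attention fusion network
#'
#' One fully connected projection per modality block maps each processed
#' 128-dimensional block to a `proj_dim` vector; the projections are
#' stacked as a length-`n_blocks` sequence ("combined vertically"),
#' passed through a self-attention layer, flattened, and scored by a
#' fully connected head with a logistic output. Four fully connected
#' layers are used in total: with fewer than three blocks the spare
#' layers form a shared position-wise stack between attention and head.
#'
#' @param config An [attentionConfig()].
#' @param n_blocks Number of constituent modality blocks (1-3).
#' @param input_dim Width of each processed block (default 128).
#' @param seed Integer seed for weight initialization.
#' @return A `FusionNet` predictor (untrained).
#' @export
buildFusionNet <- function(config = attentionConfig(), n_blocks,
                           input_dim = 128L, seed = 1L) {
  stopifnot(n_blocks %in% 1:3)
  p <- config$proj_dim; a <- config$att_dim
  params <- withSeed(seed, {
    pr <- list()
    for (b in seq_len(n_blocks)) {
      pr[[paste0("projW", b)]] <- .glorot(input_dim, p)
      pr[[paste0("projb", b)]] <- rep(0, p)
    }
    for (j in seq_len(3L - n_blocks)) {
      pr[[paste0("extraW", j)]] <- .glorot(p, p)
      pr[[paste0("extrab", j)]] <- rep(0, p)
    }
    pr$Wq <- .glorot(p, a); pr$Wk <- .glorot(p, a); pr$Wv <- .glorot(p, p)
    # zero-initialised head: an untrained net scores exactly 0.5
    pr$headW <- matrix(0, n_blocks * p, 1L)
    pr$headb <- 0
    pr
  })
  structure(list(type = "fusion", params = params, config = config,
                 n_blocks = n_blocks, input_dim = input_dim,
                 trained = FALSE),
            class = c("FusionNet", "ChemFusionNet"))
}

# Forward pass on a fused matrix (n x n_blocks*input_dim).
# Attention here runs across the block axis (seq length = n_blocks), so
# it is vectorised over samples with per-position matrices.
.fusion_forward <- function(net, x, keep_cache = FALSE) {
  P <- net$params; B <- net$n_blocks; d <- net$input_dim
  p <- net$config$proj_dim; a <- net$config$att_dim
  n <- nrow(x)
  H <- vector("list", B)
  for (b in seq_len(B)) {
    xb <- x[, ((b - 1L) * d + 1L):(b * d), drop = FALSE]
    Zb <- sweep(xb %*% P[[paste0("projW", b)]], 2,
                -P[[paste0("projb", b)]])
    H[[b]] <- .relu(Zb)
  }
  Q <- lapply(H, function(h) h %*% P$Wq)
  K <- lapply(H, function(h) h %*% P$Wk)
  V <- lapply(H, function(h) h %*% P$Wv)
  scl <- sqrt(a)
  S <- array(0, c(n, B, B))
  for (i in seq_len(B)) for (j in seq_len(B))
    S[, i, j] <- rowSums(Q[[i]] * K[[j]]) / scl
  A <- array(0, c(n, B, B))
  for (i in seq_len(B)) {
    Si <- matrix(S[, i, ], n, B)
    A[, i, ] <- .softmax_rows(Si)
  }
  O <- vector("list", B)
  for (i in seq_len(B)) {
    Oi <- matrix(0, n, p)
    for (j in seq_len(B)) Oi <- Oi + A[, i, j] * V[[j]]
    O[[i]] <- Oi
  }
  # shared position-wise pre-head stack (spare fully connected layers)
  n_extra <- 3L - B
  Ecache <- list()
  Z <- O
  for (jj in seq_len(n_extra)) {
    W <- P[[paste0("extraW", jj)]]; bb <- P[[paste0("extrab", jj)]]
    Ecache[[jj]] <- Z
    Z <- lapply(Z, function(o) .relu(sweep(o %*% W, 2, -bb)))
  }
  flat <- do.call(cbind, Z)
  z <- as.numeric(flat %*% P$headW + P$headb)
  res <- list(score = .sigmoid(z), z = z)
  if (keep_cache)
    res$cache <- list(x = x, H = H, Q = Q, K = K, V = V, A = A, O = O,
                      Z = Z, Ecache = Ecache, flat = flat, scl = scl)
  res
}

# Backward pass; dz is dLoss/dlogit (length n). Returns grads.
.fusion_backward <- function(net, cache, dz) {
  P <- net$params; B <- net$n_blocks; d <- net$input_dim
  p <- net$config$proj_dim
  n <- length(dz)
  g <- list()
  g$headW <- crossprod(cache$flat, dz)
  g$headb <- sum(dz)
  dflat <- tcrossprod(dz, as.numeric(P$headW))  # n x (B*p)
  dZ <- lapply(seq_len(B), function(i)
    dflat[, ((i - 1L) * p + 1L):(i * p), drop = FALSE])
  n_extra <- 3L - B
  for (jj in rev(seq_len(n_extra))) {
    W <- P[[paste0("extraW", jj)]]; bb <- P[[paste0("extrab", jj)]]
    Zin <- cache$Ecache[[jj]]
    dW <- matrix(0, p, p); db <- rep(0, p)
    for (i in seq_len(B)) {
      pre <- sweep(Zin[[i]] %*% W, 2, -bb)
      dpre <- dZ[[i]] * (pre > 0)
      dW <- dW + crossprod(Zin[[i]], dpre)
      db <- db + colSums(dpre)
      dZ[[i]] <- dpre %*% t(W)
    }
    g[[paste0("extraW", jj)]] <- dW
    g[[paste0("extrab", jj)]] <- db
  }
  dO <- dZ
  A <- cache$A; V <- cache$V; Q <- cache$Q; K <- cache$K
  dA <- array(0, c(n, B, B))
  dV <- lapply(seq_len(B), function(j) matrix(0, n, p))
  for (i in seq_len(B)) for (j in seq_len(B)) {
    dA[, i, j] <- rowSums(dO[[i]] * V[[j]])
    dV[[j]] <- dV[[j]] + A[, i, j] * dO[[i]]
  }
  dS <- array(0, c(n, B, B))
  for (i in seq_len(B)) {
    Ai <- matrix(A[, i, ], n, B)
    dAi <- matrix(dA[, i, ], n, B)
    dS[, i, ] <- Ai * (dAi - rowSums(dAi * Ai))
  }
  a_dim <- ncol(P$Wq)
  dQ <- lapply(seq_len(B), function(i) matrix(0, n, a_dim))
  dK <- lapply(seq_len(B), function(j) matrix(0, n, a_dim))
  for (i in seq_len(B)) for (j in seq_len(B)) {
    dQ[[i]] <- dQ[[i]] + dS[, i, j] * K[[j]] / cache$scl
    dK[[j]] <- dK[[j]] + dS[, i, j] * Q[[i]] / cache$scl
  }
  H <- cache$H
  g$Wq <- Reduce(`+`, Map(function(h, dq) crossprod(h, dq), H, dQ))
  g$Wk <- Reduce(`+`, Map(function(h, dk) crossprod(h, dk), H, dK))
  g$Wv <- Reduce(`+`, Map(function(h, dv) crossprod(h, dv), H, dV))
  for (b in seq_len(B)) {
    dH <- dQ[[b]] %*% t(P$Wq) + dK[[b]] %*% t(P$Wk) + dV[[b]] %*% t(P$Wv)
    xb <- cache$x[, ((b - 1L) * d + 1L):(b * d), drop = FALSE]
    pre <- sweep(xb %*% P[[paste0("projW", b)]], 2,
                 -P[[paste0("projb", b)]])
    dpre <- dH * (pre > 0)
    g[[paste0("projW", b)]] <- crossprod(xb, dpre)
    g[[paste0("projb", b)]] <- colSums(dpre)
  }
  g
}
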