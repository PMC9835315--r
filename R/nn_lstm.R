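#' Build the SMILES sequence network
#'
#' Embedding layer (dimension 100, padding id 0 maps to a fixed zero
#' vector), four stacked LSTM layers, scaled dot-product self-attention
#' over the time steps with the padding positions masked out, a masked
#' mean pooling over valid positions, and a fully connected head with a
#' logistic output.
#'
#' @param config An [attentionConfig()].
#' @param vocabulary Token vocabulary from [buildVocabulary()].
#' @param seed Integer seed for weight initialization.
#' @return A `SmilesNet` predictor (untrained).
#' @export
buildSmilesNet <- function(config = attentionConfig(), vocabulary,
                           seed = 1L) {
  V <- length(vocabulary)  # includes <pad>
  e <- config$embedding_dim; h <- config$lstm_hidden
  L <- config$lstm_layers; a <- config$att_dim
  params <- withSeed(seed, {
    pr <- list(E = rbind(rep(0, e), .glorot(V - 1L, e)))
    for (l in seq_len(L)) {
      din <- if (l == 1L) e else h
      pr[[paste0("W", l)]] <- .glorot(din, 4L * h)
      pr[[paste0("U", l)]] <- .glorot(h, 4L * h)
      bias <- rep(0, 4L * h)
      bias[(h + 1L):(2L * h)] <- 1  # forget-gate bias init
      pr[[paste0("b", l)]] <- bias
    }
    pr$Wq <- .glorot(h, a); pr$Wk <- .glorot(h, a); pr$Wv <- .glorot(h, h)
    # zero-initialised head: an untrained net scores exactly 0.5
    pr$headW <- matrix(0, h, 1L)
    pr$headb <- 0
    pr
  })
  structure(list(type = "smiles", params = params, config = config,
                 vocab_size = V, trained = FALSE),
            class = c("SmilesNet", "ChemFusionNet"))
}

# Forward through the stacked LSTM: returns per-step hidden states of the
# top layer plus caches for BPTT. X is an n x T integer matrix.
.smiles_forward <- function(net, X, lengths, keep_cache = FALSE) {
  P <- net$params
  h <- net$config$lstm_hidden; L <- net$config$lstm_layers
  n <- nrow(X)
  if (any(lengths < 1L)) stop("all-pad input: sequence of length 0")
  Tm <- max(lengths)
  X <- X[, seq_len(Tm), drop = FALSE]
  layer_in <- lapply(seq_len(Tm), function(t) P$E[X[, t] + 1L, , drop = FALSE])
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    W <- P[[paste0("W", l)]]; U <- P[[paste0("U", l)]]
    b <- P[[paste0("b", l)]]
    ht <- matrix(0, n, h); ct <- matrix(0, n, h)
    Hs <- vector("list", Tm)
    cache <- if (keep_cache) vector("list", Tm)
    for (t in seq_len(Tm)) {
      z <- layer_in[[t]] %*% W + ht %*% U
      z <- sweep(z, 2, -b)
      i_g <- .sigmoid(z[, 1:h, drop = FALSE])
      f_g <- .sigmoid(z[, (h + 1L):(2L * h), drop = FALSE])
      g_g <- tanh(z[, (2L * h + 1L):(3L * h), drop = FALSE])
      o_g <- .sigmoid(z[, (3L * h + 1L):(4L * h), drop = FALSE])
      c_new <- f_g * ct + i_g * g_g
      tc <- tanh(c_new)
      h_new <- o_g * tc
      if (keep_cache)
        cache[[t]] <- list(x = layer_in[[t]], h_prev = ht, c_prev = ct,
                           i = i_g, f = f_g, g = g_g, o = o_g, tc = tc)
      ht <- h_new; ct <- c_new
      Hs[[t]] <- h_new
    }
    if (keep_cache) caches[[l]] <- cache
    layer_in <- Hs
  }
  list(H = layer_in, caches = caches, X = X, Tm = Tm)
}

# BPTT through one LSTM layer. dH: list over t of n x h gradients w.r.t.
# that layer's outputs. Returns dX (list over t) and parameter grads.
.lstm_backward <- function(cache, W, U, dH) {
  Tm <- length(dH)
  n <- nrow(dH[[1]]); h <- ncol(dH[[1]])
  din <- nrow(W)
  dW <- matrix(0, din, 4L * h); dU <- matrix(0, h, 4L * h)
  db <- rep(0, 4L * h)
  dX <- vector("list", Tm)
  dh_next <- matrix(0, n, h); dc_next <- matrix(0, n, h)
  for (t in rev(seq_len(Tm))) {
    cc <- cache[[t]]
    dh <- dH[[t]] + dh_next
    do_g <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_g * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$x, dz)
    dU <- dU + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(W)
    dh_next <- dz %*% t(U)
    dc_next <- dc * cc$f
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

# Full forward to scores; per-sample attention over time with pad mask
# and masked mean pooling.
.smilesnet_forward <- function(net, X, lengths, keep_cache = FALSE) {
  P <- net$params
  fw <- .smiles_forward(net, X, lengths, keep_cache)
  n <- nrow(fw$X); Tm <- fw$Tm
  h <- net$config$lstm_hidden
  H3 <- array(unlist(fw$H), c(n, h, Tm))
  pooled <- matrix(0, n, h)
  att <- if (keep_cache) vector("list", n)
  for (s in seq_len(n)) {
    len <- min(lengths[s], Tm)
    Hi <- t(matrix(H3[s, , seq_len(len)], h, len))
    at <- selfAttention(Hi, P$Wq, P$Wk, P$Wv)
    pooled[s, ] <- colMeans(at$output)
    if (keep_cache) att[[s]] <- at
  }
  z <- as.numeric(pooled %*% P$headW + P$headb)
  res <- list(score = .sigmoid(z), z = z)
  if (keep_cache)
    res$cache <- list(fw = fw, att = att, pooled = pooled, H3 = H3,
                      lengths = pmin(lengths, Tm), n = n, Tm = Tm)
  res
}

.smilesnet_backward <- function(net, cache, dz) {
  P <- net$params
  h <- net$config$lstm_hidden; L <- net$config$lstm_layers
  n <- cache$n; Tm <- cache$Tm
  g <- list()
  g$headW <- crossprod(cache$pooled, dz)
  g$headb <- sum(dz)
  dpooled <- tcrossprod(dz, as.numeric(P$headW))  # n x h
  dH <- lapply(seq_len(Tm), function(t) matrix(0, n, h))
  g$Wq <- 0 * P$Wq; g$Wk <- 0 * P$Wk; g$Wv <- 0 * P$Wv
  for (s in seq_len(n)) {
    len <- cache$lengths[s]
    at <- cache$att[[s]]
    dO <- matrix(rep(dpooled[s, ] / len, each = len), len, h)
    bk <- .attention_backward(dO, at$cache, P$Wq, P$Wk, P$Wv)
    g$Wq <- g$Wq + bk$dWq; g$Wk <- g$Wk + bk$dWk; g$Wv <- g$Wv + bk$dWv
    for (t in seq_len(len)) dH[[t]][s, ] <- bk$dinputs[t, ]
  }
  for (l in rev(seq_len(L))) {
    bk <- .lstm_backward(cache$fw$caches[[l]], P[[paste0("W", l)]],
                         P[[paste0("U", l)]], dH)
    g[[paste0("W", l)]] <- bk$dW
    g[[paste0("U", l)]] <- bk$dU
    g[[paste0("b", l)]] <- bk$db
    dH <- bk$dX
  }
  # embedding gradient; row 1 (<pad>) stays frozen at zero
  dE <- 0 * P$E
  X <- cache$fw$X
  for (t in seq_len(Tm)) {
    idx <- X[, t] + 1L
    upd <- rowsum(dH[[t]], group = idx)
    rows <- as.integer(rownames(upd))
    dE[rows, ] <- dE[rows, ] + upd
  }
  dE[1, ] <- 0
  g$E <- dE
  g
}
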