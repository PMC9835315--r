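# Numeric core for the two attention networks: parameter init, Adam,
# dense/ReLU/softmax primitives with hand-derived gradients. All
# randomness flows through R's RNG so seeded runs are bit-reproducible.

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

.relu <- function(x) (x > 0) * x

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with -Inf masking support.
.softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e[is.na(e)] <- 0  # rows that are entirely -Inf
  e / pmax(rowSums(e), .Machine$double.eps)
}

# Binary cross-entropy on sigmoid scores; returns loss and dz (gradient
# at the pre-sigmoid logit, already averaged over the batch).
.bce <- function(z, y) {
  s <- .sigmoid(z)
  eps <- 1e-12
  loss <- -mean(y * log(s + eps) + (1 - y) * log(1 - s + eps))
  list(loss = loss, s = s, dz = (s - y) / length(y))
}

# Adam optimizer over a flat named list of parameter arrays.
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Accumulate grads2 into grads1 (same shapes).
.acc_grads <- function(g1, g2) {
  for (k in names(g2)) {
    g1[[k]] <- if (is.null(g1[[k]])) g2[[k]] else g1[[k]] + g2[[k]]
  }
  g1
}

#' Scaled dot-product self-attention (single head)
#'
#' Queries, keys and values are learned linear maps of the inputs; the
#' attention weights are the row-softmax of \eqn{QK^T/\sqrt{d}} and the
#' output is their weighted sum of values. `mask` marks valid key
#' positions (padding positions receive zero weight).
#'
#' @param inputs A `seq_len x d` matrix (one sequence).
#' @param Wq,Wk Projections `d x d_att`.
#' @param Wv Value projection `d x d_v`.
#' @param mask Logical vector of valid positions (default all).
#' @return List with `output` (`seq_len x d_v`), `weights`
#'   (`seq_len x seq_len`, rows summing to 1), and a cache for the
#'   backward pass.
#' @export
selfAttention <- function(inputs, Wq, Wk, Wv, mask = NULL) {
  Q <- inputs %*% Wq
  K <- inputs %*% Wk
  V <- inputs %*% Wv
  scl <- sqrt(ncol(Wq))
  S <- tcrossprod(Q, K) / scl
  if (!is.null(mask) && !all(mask)) S[, !mask] <- -Inf
  A <- .softmax_rows(S)
  list(output = A %*% V, weights = A,
       cache = list(inputs = inputs, Q = Q, K = K, V = V, A = A, scl = scl))
}

# Backward pass of selfAttention; dout is d(loss)/d(output).
# Returns gradients for inputs and the three projection matrices.
.attention_backward <- function(dout, cache, Wq, Wk, Wv) {
  A <- cache$A
  dV <- crossprod(A, dout)
  dA <- tcrossprod(dout, cache$V)
  # softmax Jacobian per row: dS = A * (dA - rowSums(dA * A))
  dS <- A * (dA - rowSums(dA * A))
  dQ <- (dS %*% cache$K) / cache$scl
  dK <- (crossprod(dS, cache$Q)) / cache$scl
  dinputs <- dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  list(dinputs = dinputs,
       dWq = crossprod(cache$inputs, dQ),
       dWk = crossprod(cache$inputs, dK),
       dWv = crossprod(cache$inputs, dV))
}

#' Default configuration of the attention networks
#'
#' The embedding dimension (100) and LSTM depth (4) of the SMILES network
#' are fixed design constants; everything else is tunable.
#'
#' @param ... Overrides of the defaults.
#' @return Named list: `proj_dim` (fusion projection width), `att_dim`
#'   (attention dimension), `lstm_hidden`, `embedding_dim` (fixed 100),
#'   `lstm_layers` (fixed 4), `dropout`, `lr`, `batch_size`,
#'   `max_epochs`, `patience`.
#' @export
attentionConfig <- function(...) {
  cfg <- list(proj_dim = 64L, att_dim = 32L, lstm_hidden = 64L,
              embedding_dim = 100L, lstm_layers = 4L, dropout = 0,
              lr = 1e-3, batch_size = 64L, max_epochs = 200L,
              patience = 10L)
  over <- list(...)
  if (!is.null(over$embedding_dim) && over$embedding_dim != 100L)
    stop("embedding_dim is fixed at 100")
  if (!is.null(over$lstm_layers) && over$lstm_layers != 4L)
    stop("lstm_layers is fixed at 4")
  modifyList(cfg, over)
}
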