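#' Exact t-SNE embedding
#'
#' A compact exact (O(n^2)) t-distributed stochastic neighbour embedding:
#' Gaussian input affinities calibrated per point to the target
#' perplexity by bisection, symmetrised; Student-t output affinities;
#' gradient descent with momentum (0.5 then 0.8 after iteration 250) and
#' early exaggeration (factor 4 for the first 100 iterations). Intended
#' for the moderate set sizes of chemical-space maps.
#'
#' @param x Numeric matrix (rows = points). Inputs wider than 50 columns
#'   are first reduced by PCA (the usual t-SNE preprocessing).
#' @param dims Output dimensionality (default 2).
#' @param perplexity Target perplexity (default 30; reduced automatically
#'   if `3 * perplexity >= n - 1`).
#' @param n_iter Gradient-descent iterations (default 400).
#' @param eta Learning rate (default 200).
#' @param seed Integer seed (the embedding is deterministic given it).
#' @return An n x `dims` coordinate matrix.
#' @export
tsneEmbed <- function(x, dims = 2L, perplexity = 30, n_iter = 400L,
                      eta = 200, seed = 1L) {
  n <- nrow(x)
  stopifnot(n >= 4L)
  perplexity <- min(perplexity, (n - 1) / 3)
  if (ncol(x) > 50L) {
    ctr <- colMeans(x)
    sv <- svd(sweep(x, 2, ctr), nu = 0, nv = min(50L, n - 1L))
    x <- sweep(x, 2, ctr) %*% sv$v
  }
  D <- sqDistMatrix(x)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- withSeed(seed, matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  inc <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  exagg <- 4
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100L) P * exagg else P
    num <- 1 / (1 + sqDistMatrix(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it <= 250L) 0.5 else 0.8
    # adaptive per-coordinate gains stabilise the descent
    gains <- pmax(0.01, ifelse(sign(grad) != sign(inc),
                               gains + 0.2, gains * 0.8))
    inc <- mom * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
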