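#' Linear classifier trained by stochastic gradient descent
#'
#' Minimal SGD linear model with logistic (default) or hinge loss and L2
#' regularisation, one example at a time with a `1/(1 + lambda * eta0 * t)`
#' learning-rate decay; the per-epoch shuffle is seeded, so the fit is
#' deterministic under a fixed seed.
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 labels.
#' @param lambda L2 penalty (default 1e-4).
#' @param epochs Passes over the data (default 20).
#' @param eta0 Initial learning rate (default 0.01).
#' @param loss `"log"` or `"hinge"`.
#' @param seed Integer seed for the shuffles.
#' @return An `sgdlinear` fit (weights, intercept, loss; for hinge loss,
#'   the min-max score calibration range fitted on the training margins).
#' @export
sgdFit <- function(x, y, lambda = 1e-4, epochs = 20L, eta0 = 0.01,
                   loss = c("log", "hinge"), seed = 1L) {
  loss <- match.arg(loss)
  y2 <- ifelse(y == 1L, 1, -1)
  n <- nrow(x); p <- ncol(x)
  w <- rep(0, p); b <- 0; t <- 0
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- eta0 / (1 + lambda * eta0 * t)
        m <- y2[i] * (sum(x[i, ] * w) + b)
        g <- if (loss == "log") -y2[i] * stats::plogis(-m)
             else if (m < 1) -y2[i] else 0
        w <- w - eta * (lambda * w + g * x[i, ])
        b <- b - eta * g
      }
    }
  })
  fit <- list(w = w, b = b, loss = loss)
  if (loss == "hinge") {
    margins <- as.numeric(x %*% w + b)
    fit$range <- range(margins)
  }
  structure(fit, class = "sgdlinear")
}

#' @rdname sgdFit
#' @param fit An `sgdlinear` fit.
#' @return `sgdScore` returns class-1 scores in `[0, 1]` (logistic
#'   probability, or the min-max-calibrated margin for hinge loss).
#' @export
sgdScore <- function(fit, x) {
  m <- as.numeric(x %*% fit$w + fit$b)
  if (fit$loss == "log") return(stats::plogis(m))
  r <- fit$range
  if (diff(r) < 1e-12) return(rep(0.5, length(m)))
  pmin(1, pmax(0, (m - r[1]) / diff(r)))
}
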