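#' Train an attention network
#'
#' Mini-batch Adam on binary cross-entropy with seeded shuffling and
#' early stopping on validation AUC: training stops when the validation
#' AUC has not improved for `patience` epochs (or at `max_epochs`), and
#' the weights of the best epoch are restored. A non-finite loss aborts
#' with the training log attached.
#'
#' @param net A [buildFusionNet()] or [buildSmilesNet()] predictor.
#' @param x Training input: numeric matrix (fusion) or token list with
#'   `sequences`/`lengths` (SMILES network).
#' @param y 0/1 training labels.
#' @param x_val,y_val Validation input and labels (same forms).
#' @param seed Integer seed for shuffling (weight init is seeded at build
#'   time).
#' @return The trained net, with `$log` (per-epoch loss and validation
#'   AUC) and `$best_epoch`.
#' @export
trainNetwork <- function(net, x, y, x_val, y_val, seed = 1L) {
  cfg <- net$config
  n <- if (net$type == "fusion") nrow(x) else nrow(x$sequences)
  y <- as.numeric(y)
  adam <- .adam_init(net$params)
  best <- list(auc = -Inf, params = net$params, epoch = 0L)
  log <- NULL
  epoch_seeds <- deriveSeeds(seed, cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- withSeed(epoch_seeds[epoch], sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_loss <- 0
    for (bi in batches) {
      if (net$type == "fusion") {
        fwd <- .fusion_forward(net, x[bi, , drop = FALSE], keep_cache = TRUE)
      } else {
        fwd <- .smilesnet_forward(net, x$sequences[bi, , drop = FALSE],
                                  x$lengths[bi], keep_cache = TRUE)
      }
      bce <- .bce(fwd$z, y[bi])
      if (!is.finite(bce$loss)) {
        net$log <- log
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      epoch_loss <- epoch_loss + bce$loss * length(bi)
      grads <- if (net$type == "fusion")
        .fusion_backward(net, fwd$cache, bce$dz)
      else .smilesnet_backward(net, fwd$cache, bce$dz)
      upd <- .adam_step(net$params, grads, adam, lr = cfg$lr)
      net$params <- upd$params
      adam <- upd$state
    }
    val_scores <- predictScores(net, x_val)
    val_auc <- computeMetrics(as.integer(val_scores >= 0.5), val_scores,
                              y_val)[["auc"]]
    log <- rbind(log, data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                 val_auc = val_auc))
    if (is.finite(val_auc) && val_auc > best$auc + 1e-6) {
      best <- list(auc = val_auc, params = net$params, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) break
  }
  net$params <- best$params
  net$trained <- TRUE
  net$log <- log
  net$best_epoch <- best$epoch
  net
}

#' @export
predictScores.ChemFusionNet <- function(model, x) {
  if (model$type == "fusion") {
    .fusion_forward(model, as.matrix(x))$score
  } else {
    .smilesnet_forward(model, x$sequences, x$lengths)$score
  }
}

#' @export
print.ChemFusionNet <- function(x, ...) {
  cat(sprintf("<%s> %s, %d parameters\n",
              class(x)[1], if (x$trained) "trained" else "untrained",
              sum(vapply(x$params, length, 0L))))
  invisible(x)
}
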