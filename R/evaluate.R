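#' Classification metrics: accuracy, F1 and AUC
#'
#' Accuracy is the fraction correct; F1 is `2TP / (2TP + FP + FN)` with
#' the active class (1) positive; AUC is the Mann-Whitney rank statistic
#' with midrank tie correction (a fully tied score vector gives 0.5).
#' AUC is `NA` (flagged) when the truth contains a single class.
#'
#' @param pred_label Predicted 0/1 labels.
#' @param score Continuous class-1 scores.
#' @param truth True 0/1 labels.
#' @return Named numeric vector `c(acc, f1, auc)` on the 0-1 scale.
#' @export
computeMetrics <- function(pred_label, score, truth) {
  stopifnot(length(pred_label) == length(truth),
            length(score) == length(truth))
  truth <- as.integer(truth); pred_label <- as.integer(pred_label)
  acc <- mean(pred_label == truth)
  tp <- sum(pred_label == 1L & truth == 1L)
  fp <- sum(pred_label == 1L & truth == 0L)
  fn <- sum(pred_label == 0L & truth == 1L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  auc <- if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: truth contains a single class")
    NA_real_
  } else {
    r <- rank(score, ties.method = "average")
    (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  c(acc = acc, f1 = f1, auc = auc)
}

#' Welch two-sample t-test on per-seed metric vectors
#'
#' Unequal-variance (Welch) two-sided t-test computed in closed form.
#' Degenerate conventions for repeated deterministic fits: when both
#' vectors have zero variance and equal means the result is `t = 0,
#' p = 1`; with unequal means the difference is deterministic and flagged
#' significant by convention (`p = 0`).
#'
#' @param a,b Numeric vectors (per-seed metric values), length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return A `data.frame` with `t`, `df`, `p`, `significant`,
#'   `degenerate`.
#' @export
pairwiseTTest <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  if (va == 0 && vb == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(data.frame(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                      df = NA_real_, p = if (eq) 1 else 0,
                      significant = !eq, degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(t = tstat, df = df, p = p, significant = p < alpha,
             degenerate = FALSE)
}

#' Aggregate a seeded experiment over many seeds
#'
#' Runs `run_fn(seed)` - typically the full
#' search-train-evaluate pipeline - once per seed and summarises each
#' returned metric by its mean and population SD (divisor n; the
#' convention used in the mean +/- SD report tables; set
#' `sd_type = "sample"` for divisor n-1). A failing seed is recorded and
#' the summary marked incomplete.
#'
#' @param run_fn Function of one argument (the seed) returning a named
#'   numeric vector of metrics.
#' @param seeds Distinct integer seeds (the study design uses 30).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A `MetricSummary` list: `per_seed` (data.frame), `mean`, `sd`,
#'   `n_seeds`, `complete`, `failures`.
#' @export
repeatOverSeeds <- function(run_fn, seeds, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(!anyDuplicated(seeds))
  rows <- list(); failures <- list()
  for (s in seeds) {
    res <- tryCatch(run_fn(s), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(s)]] <- conditionMessage(res)
    } else {
      rows[[as.character(s)]] <- c(seed = s, res)
    }
  }
  per_seed <- as.data.frame(do.call(rbind, rows))
  metrics <- setdiff(colnames(per_seed), "seed")
  mu <- vapply(per_seed[metrics], mean, 0)
  sdv <- vapply(per_seed[metrics], function(v) {
    if (sd_type == "population") sqrt(mean((v - mean(v))^2))
    else stats::sd(v)
  }, 0)
  structure(list(per_seed = per_seed, mean = mu, sd = sdv,
                 n_seeds = length(seeds) - length(failures),
                 complete = length(failures) == 0L, failures = failures),
            class = "MetricSummary")
}

#' @export
print.MetricSummary <- function(x, ...) {
  cat(sprintf("MetricSummary over %d seed(s)%s\n", x$n_seeds,
              if (x$complete) "" else " [INCOMPLETE]"))
  for (m in names(x$mean))
    cat(sprintf("  %s: %.2f +/- %.2f %%\n", m, 100 * x$mean[m], 100 * x$sd[m]))
  invisible(x)
}

#' Prediction overlap between two models (Venn analysis)
#'
#' Partitions the shared test set into both-correct, only-A-correct,
#' only-B-correct and both-wrong, with the overlap percentage computed as
#' shared / union separately for correct and incorrect predictions.
#'
#' @param pred_a,pred_b Predicted 0/1 labels of the two models.
#' @param truth True 0/1 labels (same compounds, same order).
#' @return An `OverlapSummary` list: `counts`, `percent` (of test size),
#'   `overlap_correct`, `overlap_incorrect`.
#' @export
predictionOverlap <- function(pred_a, pred_b, truth) {
  n <- length(truth)
  stopifnot(length(pred_a) == n, length(pred_b) == n)
  ca <- pred_a == truth; cb <- pred_b == truth
  counts <- c(both_correct = sum(ca & cb), only_a = sum(ca & !cb),
              only_b = sum(!ca & cb), both_wrong = sum(!ca & !cb))
  stopifnot(sum(counts) == n)
  list(counts = counts, percent = 100 * counts / n,
       overlap_correct = 100 * counts[["both_correct"]] /
         max(1L, sum(ca | cb)),
       overlap_incorrect = 100 * counts[["both_wrong"]] /
         max(1L, sum(!ca | !cb)))
}

#' Two-dimensional chemical-space maps
#'
#' Embeds each raw modality (descriptors, ECFP4, MACCS) into two
#' dimensions with t-SNE for visual inspection of how active and inactive
#' compounds occupy chemical space.
#'
#' @param cs A [CompoundSet-class] with raw blocks.
#' @param modalities Blocks to embed.
#' @param seed Integer seed.
#' @param perplexity,n_iter t-SNE parameters (see [tsneEmbed()]).
#' @return Named list of n x 2 coordinate matrices.
#' @export
chemspaceMap <- function(cs, modalities = c("descriptors", "ecfp4", "maccs"),
                         seed = 1L, perplexity = 30, n_iter = 400L) {
  if (length(cs) < 10L) stop("need at least 10 compounds")
  out <- lapply(modalities, function(mod) {
    m <- dropZeroVariance(featureBlock(cs, mod))
    m <- imputeNonFinite(m)$matrix
    m <- fitApplyStandardizer(m)$matrix
    tsneEmbed(m, seed = seed, perplexity = perplexity, n_iter = n_iter)
  })
  stats::setNames(out, modalities)
}
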