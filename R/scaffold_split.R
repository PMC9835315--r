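#' Conjoint representation for structural clustering
#'
#' Concatenates the standardized raw modality blocks (descriptors, MACCS,
#' ECFP4) into one wide matrix. Clustering precedes the train/test split,
#' so the standardization here is fitted on all compounds.
#'
#' @param cs A [CompoundSet-class] with raw blocks computed.
#' @param modalities Blocks to concatenate, in order.
#' @return Numeric matrix, width = sum of filtered block widths.
#' @export
conjointRepresentation <- function(cs,
                                   modalities = c("descriptors", "maccs", "ecfp4")) {
  parts <- lapply(modalities, function(mod) {
    m <- dropZeroVariance(featureBlock(cs, mod))
    m <- imputeNonFinite(m)$matrix
    fitApplyStandardizer(m)$matrix
  })
  ns <- vapply(parts, nrow, 0L)
  if (length(unique(ns)) != 1L) stop("row-count mismatch across blocks")
  do.call(cbind, parts)
}

# k-means++ seeding followed by Lloyd iterations; best of `nstart` restarts.
.kmeanspp <- function(x, k, nstart = 10L, iter.max = 50L) {
  n <- nrow(x)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(0, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1L), ]
    d2 <- sqDistMatrix(x, centers[1, , drop = FALSE])[, 1]
    for (j in seq_len(k - 1L)) {
      p <- d2 / sum(d2)
      centers[j + 1L, ] <- x[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, sqDistMatrix(x, centers[j + 1L, , drop = FALSE])[, 1])
    }
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter.max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# Calinski-Harabasz score: between/within variance ratio.
.chs <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  gm <- colMeans(x)
  w <- 0; b <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    cm <- colMeans(xi)
    w <- w + sum(sweep(xi, 2, cm)^2)
    b <- b + nrow(xi) * sum((cm - gm)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# Davies-Bouldin index: mean over clusters of worst similarity ratio.
.dbi <- function(x, labels) {
  cls <- sort(unique(labels)); k <- length(cls)
  cents <- t(vapply(cls, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(ncol(x))))
  scatter <- vapply(seq_len(k), function(i) {
    xi <- x[labels == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cents[i, ])^2)))
  }, 0)
  cd <- sqrt(sqDistMatrix(cents))
  mean(vapply(seq_len(k), function(i) {
    r <- (scatter[i] + scatter[-i]) / cd[i, -i]
    max(r)
  }, 0))
}

#' Select the cluster count by internal-index consensus
#'
#' Runs K-means (k-means++ initialization, 10 restarts) on the conjoint
#' representation for each candidate k and records the Calinski-Harabasz
#' score (CHS), Davies-Bouldin index (DBI) and mean silhouette coefficient
#' (SC). The chosen k has the highest SC, with ties broken by lowest DBI,
#' then highest CHS.
#'
#' @param mat Conjoint matrix from [conjointRepresentation()].
#' @param k_range Candidate cluster counts (within `[2, n-1]`).
#' @param seed Integer seed.
#' @param nstart Restarts per k.
#' @return A `ClusterAssignment`: list with `k`, `labels` (per compound),
#'   `quality` (data.frame of CHS/DBI/SC per k) and `fits`.
#' @export
selectClusterCount <- function(mat, k_range = 2:15, seed = 1L, nstart = 10L) {
  n <- nrow(mat)
  stopifnot(all(k_range >= 2L), all(k_range <= n - 1L))
  if (nrow(unique(mat)) < max(k_range))
    warning("fewer distinct points than largest candidate k; ",
            "degenerate variance possible")
  d <- sqrt(sqDistMatrix(mat))
  fits <- list(); quality <- NULL
  withSeed(seed, {
    for (k in k_range) {
      fit <- .kmeanspp(mat, k, nstart = nstart)
      lab <- fit$cluster
      sil <- cluster::silhouette(lab, dmatrix = d)
      quality <- rbind(quality, data.frame(
        k = k, CHS = .chs(mat, lab), DBI = .dbi(mat, lab),
        SC = mean(sil[, "sil_width"])))
      fits[[as.character(k)]] <- lab
    }
  })
  ord <- order(-quality$SC, quality$DBI, -quality$CHS)
  k_best <- quality$k[ord[1]]
  structure(list(k = k_best, labels = fits[[as.character(k_best)]],
                 quality = quality, fits = fits),
            class = "ClusterAssignment")
}

#' Create a ratio-preserving cluster hold-out split
#'
#' Holds out `n_test_clusters` whole clusters as the test set, choosing
#' among the candidate cluster subsets the one whose positive rate is
#' closest to the overall positive rate, subject to the test-set size
#' falling inside `size_band` (fraction of compounds; the band is widened
#' with a warning when no subset qualifies). The validation set is then
#' drawn compound-wise, stratified by label, from the remaining clusters.
#' No canonical SMILES can appear in two partitions, and no test-cluster
#' compound can reach train/validation.
#'
#' @param cs A labeled [CompoundSet-class].
#' @param clusters Integer cluster id per compound (e.g.
#'   `selectClusterCount(...)$labels`).
#' @param n_test_clusters Clusters to hold out (default 3).
#' @param val_fraction Fraction of all compounds used for validation
#'   (default 0.05).
#' @param size_band Acceptable test-set size as a fraction range.
#' @param seed Integer seed (validation sampling).
#' @return `cs` with `cluster` and `partition` columns; the split report
#'   (test clusters, class-ratio table) is in `metadata(cs)$split`.
#' @export
makeSplit <- function(cs, clusters, n_test_clusters = 3L,
                      val_fraction = 0.05, size_band = c(0.08, 0.16),
                      seed = 1L) {
  stopifnot(length(clusters) == length(cs))
  ids <- sort(unique(clusters))
  k <- length(ids)
  if (k <= n_test_clusters)
    stop(sprintf("need more than %d clusters, have %d", n_test_clusters, k))
  y <- activityLabels(cs)
  overall <- mean(y == 1L)
  n <- length(cs)
  subsets <- if (k <= 20L) utils::combn(ids, n_test_clusters, simplify = FALSE)
  else .greedy_subsets(clusters, y, ids, n_test_clusters, overall)
  size <- vapply(subsets, function(s) sum(clusters %in% s) / n, 0)
  dev <- vapply(subsets, function(s) {
    abs(mean(y[clusters %in% s] == 1L) - overall)
  }, 0)
  band <- size_band
  repeat {
    ok <- size >= band[1] & size <= band[2]
    if (any(ok)) break
    band <- c(band[1] / 1.5, min(1, band[2] * 1.5))
    warning(sprintf("no test subset within size band; widened to [%.3f, %.3f]",
                    band[1], band[2]))
  }
  pick <- which(ok)[which.min(dev[ok])]
  test_clusters <- subsets[[pick]]
  part <- rep("train", n)
  part[clusters %in% test_clusters] <- "test"
  rest <- which(part == "train")
  n_val <- round(val_fraction * n)
  val_idx <- withSeed(seed, {
    pos <- rest[y[rest] == 1L]; neg <- rest[y[rest] == 0L]
    n_pos <- round(n_val * length(pos) / length(rest))
    c(sample(pos, min(n_pos, length(pos))),
      sample(neg, min(n_val - n_pos, length(neg))))
  })
  part[val_idx] <- "validation"
  cd <- compoundData(cs)
  cd$cluster <- clusters
  cd$partition <- part
  compoundData(cs) <- cd
  ratio <- do.call(rbind, lapply(split(y, part), function(v)
    data.frame(n = length(v), positive_rate = mean(v == 1L))))
  md <- metadata(cs)
  md$split <- list(test_clusters = test_clusters, class_ratio = ratio,
                   overall_positive_rate = overall, seed = seed)
  metadata(cs) <- md
  cs
}

# Greedy candidate subsets for large k: grow subsets toward the overall
# positive rate from each singleton start.
.greedy_subsets <- function(clusters, y, ids, m, overall) {
  lapply(ids, function(start) {
    sel <- start
    while (length(sel) < m) {
      cand <- setdiff(ids, sel)
      dev <- vapply(cand, function(cl) {
        idx <- clusters %in% c(sel, cl)
        abs(mean(y[idx] == 1L) - overall)
      }, 0)
      sel <- c(sel, cand[which.min(dev)])
    }
    sel
  })
}

#' Persist / load a split specification
#'
#' @param cs A split [CompoundSet-class].
#' @param path CSV path (`canonical_smiles, partition, cluster`).
#' @return `writeSplitCsv` returns `path` invisibly.
#' @export
writeSplitCsv <- function(cs, path) {
  cd <- compoundData(cs)
  utils::write.csv(data.frame(canonical_smiles = cd$canonical_smiles,
                              partition = cd$partition,
                              cluster = cd$cluster),
                   path, row.names = FALSE)
  invisible(path)
}
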