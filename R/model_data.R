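#' Assemble model-ready data for one feature combination
#'
#' Extracts, for a split [CompoundSet-class], the model input of a feature
#' combination: a fused numeric matrix (combos 1-3, 5-8) or the token
#' sequences (combo 4), together with labels and partition assignment.
#'
#' @param cs A split (and, for numeric combos, preprocessed)
#'   [CompoundSet-class].
#' @param combo_id Feature combination id 1-8 ([featureCombos()]).
#' @return A `ModelData` list: `x` (matrix or token list), `y`,
#'   `partition`, `type` (`"numeric"` or `"tokens"`), `combo_id`, `origin`
#'   (per-row provenance: `"measured"` or an augmentation tag).
#' @export
makeModelData <- function(cs, combo_id) {
  part <- partitions(cs)
  if (is.null(part)) stop("CompoundSet has no partition; run makeSplit() first")
  y <- activityLabels(cs)
  if (identical(featureCombos()[[as.character(combo_id)]], "smiles")) {
    tok <- tokenizedSmiles(cs)
    if (!length(tok)) stop("no token encoding; run encodeCompoundSet() first")
    md <- list(x = tok, y = y, partition = part, type = "tokens",
               combo_id = combo_id,
               origin = rep("measured", length(y)))
  } else {
    fused <- fuseBlocks(cs, combo_id)
    md <- list(x = fused$matrix, y = y, partition = part, type = "numeric",
               combo_id = combo_id, boundaries = fused$boundaries,
               origin = rep("measured", length(y)))
  }
  structure(md, class = "ModelData")
}

.md_counts <- function(md, parts = c("train", "validation")) {
  idx <- md$partition %in% parts
  table(factor(md$y[idx], levels = c(0, 1)))
}

#' Balance the training and validation partitions
#'
#' Augments the minority class of the train and validation partitions
#' (separately, so each keeps the target ratio) up to
#' `minority:majority = target_ratio`, using one of the three strategies:
#' `"smote"` (numeric features; interpolated rows), `"decoys"`
#' (property-matched inactive compounds appended as negatives; numeric or
#' token features) or `"enumeration"` (token features; randomized SMILES
#' notations of minority compounds). The test partition is never touched.
#'
#' @param md A `ModelData` from [makeModelData()].
#' @param strategy `"smote"`, `"decoys"` or `"enumeration"`.
#' @param cs The source [CompoundSet-class] (needed for SMILES and fitted
#'   preprocessing when strategy is `"decoys"` or `"enumeration"`).
#' @param target_ratio Minority:majority ratio to reach (default 1).
#' @param k_neighbors SMOTE neighbourhood size.
#' @param pool,criteria Decoy pool SMILES and [decoyCriteria()]
#'   (strategy `"decoys"`).
#' @param seed Integer seed.
#' @return The augmented `ModelData`; synthetic rows carry `origin`
#'   `"smote"`, `"decoy"` or `"enumeration"` and never the `"test"`
#'   partition.
#' @export
balanceTrainingSets <- function(md, strategy = c("smote", "decoys", "enumeration"),
                                cs = NULL, target_ratio = 1,
                                k_neighbors = 5L, pool = NULL,
                                criteria = decoyCriteria(), seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(md, "ModelData"))
  if (strategy == "smote" && md$type != "numeric")
    stop("SMOTE applies to numeric features only")
  if (strategy == "enumeration" && md$type != "tokens")
    stop("SMILES enumeration applies to token features only")
  seeds <- deriveSeeds(seed, 2L)
  needs <- lapply(c(train = "train", validation = "validation"), function(p) {
    idx <- which(md$partition == p)
    n_pos <- sum(md$y[idx] == 1L); n_neg <- sum(md$y[idx] == 0L)
    minority <- if (n_pos < n_neg) 1L else 0L
    list(idx = idx, minority = minority,
         n_new = max(0L, round(target_ratio * max(n_pos, n_neg)) -
                       min(n_pos, n_neg)))
  })
  if (strategy == "decoys") {
    # one pool draw for both partitions so no decoy is reused across them
    total <- needs$train$n_new + needs$validation$n_new
    if (total > 0L)
      md <- .aug_decoys(md, needs, cs, pool, criteria, seeds[[1]])
    return(md)
  }
  for (p in c("train", "validation")) {
    nd <- needs[[p]]
    if (!length(nd$idx) || nd$n_new <= 0L) next
    s <- seeds[[match(p, c("train", "validation"))]]
    min_idx <- nd$idx[md$y[nd$idx] == nd$minority]
    md <- switch(strategy,
      smote = .aug_smote(md, min_idx, nd$n_new, k_neighbors, p, nd$minority, s),
      enumeration = .aug_enum(md, min_idx, nd$n_new, cs, p, nd$minority, s))
  }
  md
}

.aug_smote <- function(md, min_idx, n_new, k_neighbors, part, minority, seed) {
  sm <- smote(md$x[min_idx, , drop = FALSE], n_new, k_neighbors, seed)
  md$x <- rbind(md$x, sm$rows)
  md$y <- c(md$y, rep(minority, n_new))
  md$partition <- c(md$partition, rep(part, n_new))
  md$origin <- c(md$origin, rep("smote", n_new))
  md
}

.aug_enum <- function(md, min_idx, n_new, cs, part, minority, seed) {
  if (is.null(cs)) stop("enumeration needs the source CompoundSet")
  smi <- canonicalSmiles(cs)[min_idx]
  per <- ceiling(n_new / length(smi))
  vars <- enumerateSmiles(smi, per, seed)
  cand <- data.frame(smiles = unlist(vars),
                     parent = rep(seq_along(smi), lengths(vars)))
  vocab <- md$x$vocabulary
  known <- vapply(tokenizeSmiles(cand$smiles),
                  function(t) all(t %in% names(vocab)) &&
                    length(t) <= ncol(md$x$sequences), NA)
  if (any(!known))
    message(sum(!known), " variant(s) dropped: out-of-vocabulary symbols")
  cand <- cand[known, , drop = FALSE]
  # interleave parents so each contributes evenly, then truncate
  cand <- cand[order(stats::ave(cand$parent, cand$parent, FUN = seq_along),
                     cand$parent), , drop = FALSE]
  if (nrow(cand) < n_new)
    warning(sprintf("enumeration produced %d usable variants (< %d needed)",
                    nrow(cand), n_new))
  cand <- utils::head(cand, n_new)
  enc <- encodeSmiles(cand$smiles, vocab, max_len = ncol(md$x$sequences))
  md$x$sequences <- rbind(md$x$sequences, enc$sequences)
  md$x$lengths <- c(md$x$lengths, enc$lengths)
  md$y <- c(md$y, rep(minority, nrow(cand)))
  md$partition <- c(md$partition, rep(part, nrow(cand)))
  md$origin <- c(md$origin, rep("enumeration", nrow(cand)))
  md
}

.aug_decoys <- function(md, needs, cs, pool, criteria, seed) {
  if (is.null(cs) || is.null(pool))
    stop("decoy strategy needs the source CompoundSet and a candidate pool")
  actives <- canonicalSmiles(cs)[activityLabels(cs) == 1L &
                                   partitions(cs) %in% c("train", "validation")]
  criteria$count <- needs$train$n_new + needs$validation$n_new
  sel <- selectDecoys(actives, pool, criteria, seed)
  dec <- sel$decoys
  if (!length(dec)) {
    warning("no decoys survived the filters; partitions left unbalanced")
    return(md)
  }
  part <- rep(c("train", "validation"),
              c(min(needs$train$n_new, length(dec)),
                max(0L, min(needs$validation$n_new,
                            length(dec) - needs$train$n_new))))
  dec <- dec[seq_along(part)]
  if (md$type == "numeric") {
    new_cs <- CompoundSet(unique(dec))
    new_cs <- computeFeatureBlocks(new_cs)
    states <- metadata(cs)$preprocess$states
    if (is.null(states)) stop("decoy strategy needs fitted preprocessing states")
    target_dim <- metadata(cs)$preprocess$target_dim
    for (mod in c("descriptors", "ecfp4", "maccs"))
      featureBlock(new_cs, paste0(mod, ".", target_dim)) <-
        applyPreprocess(states[[mod]], featureBlock(new_cs, mod))
    combos <- featureCombos()[[as.character(md$combo_id)]]
    rows <- do.call(cbind, lapply(combos, function(mod)
      featureBlock(new_cs, paste0(mod, ".", target_dim))))
    rows <- rows[match(dec, canonicalSmiles(new_cs)), , drop = FALSE]
    md$x <- rbind(md$x, rows)
  } else {
    vocab <- md$x$vocabulary
    known <- vapply(tokenizeSmiles(dec),
                    function(t) all(t %in% names(vocab)) &&
                      length(t) <= ncol(md$x$sequences), NA)
    if (any(!known))
      message(sum(!known), " decoy(s) dropped: out-of-vocabulary symbols")
    dec <- dec[known]; part <- part[known]
    enc <- encodeSmiles(dec, vocab, max_len = ncol(md$x$sequences))
    md$x$sequences <- rbind(md$x$sequences, enc$sequences)
    md$x$lengths <- c(md$x$lengths, enc$lengths)
  }
  n_add <- length(dec)
  md$y <- c(md$y, rep(0L, n_add))
  md$partition <- c(md$partition, part)
  md$origin <- c(md$origin, rep("decoy", n_add))
  md
}
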