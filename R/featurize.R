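#' Compute the physicochemical descriptor block
#'
#' Computes the pinned panel of 208 physicochemical descriptors for every
#' compound and stores it as feature block `"descriptors"`. The panel is
#' fixed by descriptor name (shipped in `extdata/descriptor_panel.txt`) so
#' that the column set is stable across toolkit releases. Descriptors that
#' fail on a molecule become `NaN` and are median-imputed during
#' preprocessing; a molecule whose whole row fails is dropped with a
#' report.
#'
#' @param cs A [CompoundSet-class].
#' @param panel Character vector of descriptor names; defaults to the
#'   shipped 208-name panel.
#' @return `cs` with the `"descriptors"` block added (possibly with failed
#'   compounds removed).
#' @export
computeDescriptors <- function(cs, panel = descriptorPanel()) {
  smi <- canonicalSmiles(cs)
  panelfile <- tempfile("panel")
  on.exit(unlink(panelfile))
  writeLines(panel, panelfile)
  out <- .rdkit("desc", smi, shQuote(panelfile))
  bad <- .rdkit_errors(out)
  if (any(bad)) {
    message(sum(bad), " compound(s) dropped: descriptor computation failed")
    cs <- cs[!bad]
    out <- out[!bad]
  }
  m <- .tsv_to_matrix(out, length(panel))
  colnames(m) <- panel
  featureBlock(cs, "descriptors") <- m
  cs
}

#' The pinned descriptor panel
#'
#' @return Character vector of the 208 descriptor names computed by
#'   [computeDescriptors()].
#' @export
descriptorPanel <- function() {
  readLines(system.file("extdata", "descriptor_panel.txt",
                        package = "ChemFusion"))
}

#' Compute a fingerprint block
#'
#' MACCS structural keys (166 bits) or Morgan/ECFP4 fingerprints
#' (radius 2 hashed to 2048 bits), stored as feature block `"maccs"` or
#' `"ecfp4"`.
#'
#' @param cs A [CompoundSet-class].
#' @param kind `"maccs"` or `"ecfp4"`.
#' @return `cs` with the binary block added.
#' @export
computeFingerprint <- function(cs, kind = c("maccs", "ecfp4")) {
  kind <- match.arg(kind)
  out <- .rdkit("fp", canonicalSmiles(cs), kind)
  bad <- .rdkit_errors(out)
  if (any(bad)) {
    message(sum(bad), " compound(s) dropped: fingerprint computation failed")
    cs <- cs[!bad]
    out <- out[!bad]
  }
  m <- .bits_to_matrix(out)
  stopifnot(ncol(m) == if (kind == "maccs") 166L else 2048L)
  featureBlock(cs, kind) <- m
  cs
}

#' Compute all three raw numeric modalities
#'
#' @param cs A [CompoundSet-class].
#' @return `cs` with `"descriptors"`, `"maccs"` and `"ecfp4"` blocks.
#' @export
computeFeatureBlocks <- function(cs) {
  cs <- computeDescriptors(cs)
  cs <- computeFingerprint(cs, "maccs")
  computeFingerprint(cs, "ecfp4")
}

#' Remove zero-variance features (fit on training rows)
#'
#' Columns that are constant on the fit rows (which includes the all-zero
#' descriptor columns) are removed; the kept indices are recorded so the
#' identical column set is applied to validation and test rows.
#'
#' @param mat Numeric matrix.
#' @param fit_rows Integer row indices the filter is fitted on (default:
#'   all rows).
#' @return The reduced matrix with attribute `kept` (kept column indices).
#' @export
dropZeroVariance <- function(mat, fit_rows = seq_len(nrow(mat))) {
  stopifnot(nrow(mat) >= 1L)
  sub <- mat[fit_rows, , drop = FALSE]
  rng <- matrixStats_colRange(sub)
  # a column is constant if its finite min equals its finite max;
  # columns that are non-finite everywhere are also dropped
  keep <- unname(which(is.finite(rng[1, ]) & rng[1, ] != rng[2, ]))
  if (!length(keep)) stop("all columns are constant on the fit rows")
  structure(mat[, keep, drop = FALSE], kept = keep)
}

# colRanges without matrixStats: min/max per column ignoring NaN
matrixStats_colRange <- function(m) {
  apply(m, 2, function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) c(NA_real_, NA_real_) else range(x)
  })
}

#' Impute non-finite feature values by fit-row column medians
#'
#' @param mat Numeric matrix possibly containing `NaN`/`Inf`.
#' @param fit_rows Rows whose medians define the imputation values.
#' @return List with `matrix` (imputed) and `medians`.
#' @export
imputeNonFinite <- function(mat, fit_rows = seq_len(nrow(mat))) {
  med <- apply(mat[fit_rows, , drop = FALSE], 2, function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) 0 else stats::median(x)
  })
  bad <- !is.finite(mat)
  if (any(bad)) {
    message(sum(bad), " non-finite feature value(s) imputed by fit-row medians")
    idx <- which(bad, arr.ind = TRUE)
    mat[bad] <- med[idx[, 2]]
  }
  list(matrix = mat, medians = med)
}

#' Fit and apply feature standardization
#'
#' Centers and scales every column to mean 0 and (population) SD 1,
#' computed on the fit rows only; other rows are transformed with the fit
#' statistics, keeping preprocessing leakage-free.
#'
#' @param mat Numeric matrix (no zero-variance columns; run
#'   [dropZeroVariance()] first).
#' @param fit_rows Rows to fit on (at least 2).
#' @return List with `matrix` (all rows transformed), `center`, `scale`.
#' @export
fitApplyStandardizer <- function(mat, fit_rows = seq_len(nrow(mat))) {
  stopifnot(length(fit_rows) >= 2L)
  sub <- mat[fit_rows, , drop = FALSE]
  center <- colMeans(sub)
  n <- nrow(sub)
  scl <- sqrt(colMeans(sweep(sub, 2, center)^2))  # population SD
  zero <- scl < 1e-12
  if (any(zero))
    stop("zero-variance column(s) at fit time: ",
         paste(utils::head(which(zero), 5), collapse = ", "))
  out <- sweep(sweep(mat, 2, center), 2, scl, "/")
  list(matrix = out, center = center, scale = scl)
}

applyStandardizer <- function(mat, center, scale)
  sweep(sweep(mat, 2, center), 2, scale, "/")

# Tolerant variant for post-PCA scores: principal components beyond the
# fit-data rank carry no training information, so they are zeroed for
# every row (projections of held-out rows onto them would be pure
# leakage-free noise) instead of erroring.
.standardize_tolerant <- function(mat, fit_rows) {
  sub <- mat[fit_rows, , drop = FALSE]
  center <- colMeans(sub)
  scl <- sqrt(colMeans(sweep(sub, 2, center)^2))
  dead <- scl < 1e-8
  center[dead] <- 0
  scl[dead] <- 1
  out <- applyStandardizer(mat, center, scl)
  out[, dead] <- 0
  list(matrix = out, center = center, scale = scl, dead = dead)
}

#' PCA projection to a fixed dimensionality
#'
#' Fits principal components on the fit rows (centered, unscaled) and
#' projects every row onto the leading `target_dim` components, ordered by
#' non-increasing explained variance.
#'
#' @param mat Numeric matrix; `ncol(mat)` must be at least `target_dim`.
#' @param fit_rows Rows to fit on; must number more than `target_dim`.
#' @param target_dim Output width (default 128).
#' @return List with `matrix` (n x target_dim scores), `rotation`,
#'   `center` and `explained_variance`.
#' @export
pcaReduce <- function(mat, fit_rows = seq_len(nrow(mat)), target_dim = 128L) {
  if (ncol(mat) < target_dim)
    stop(sprintf("input dimension %d below target %d", ncol(mat), target_dim))
  if (length(fit_rows) <= target_dim)
    stop("need more fit rows than target dimensions")
  sub <- mat[fit_rows, , drop = FALSE]
  center <- colMeans(sub)
  sv <- svd(sweep(sub, 2, center), nu = 0, nv = target_dim)
  ev <- (sv$d^2 / length(fit_rows))[seq_len(target_dim)]
  list(matrix = sweep(mat, 2, center) %*% sv$v,
       rotation = sv$v, center = center,
       explained_variance = ev)
}

#' Preprocess the three numeric modalities to 128-dimensional blocks
#'
#' Runs the full numeric preprocessing chain per modality: zero-variance
#' filter, median imputation of non-finite descriptor values,
#' standardization (descriptors only, before PCA), PCA projection to
#' `target_dim`, and a final standardization of the projected scores. All
#' statistics are fitted on `fit_rows` only (default: the train and
#' validation partitions when a split is present, else all rows) and the
#' fitted state is stored in `metadata(cs)$preprocess` so held-out or new
#' compounds are transformed without refitting.
#'
#' @param cs A [CompoundSet-class] with raw blocks computed.
#' @param fit_scope `"train"` (fit on train+validation; default) or
#'   `"all"`.
#' @param target_dim Projected width per modality (default 128).
#' @return `cs` with processed blocks `"descriptors.128"`, `"ecfp4.128"`,
#'   `"maccs.128"` added.
#' @export
preprocessFeatures <- function(cs, fit_scope = c("train", "all"),
                               target_dim = 128L) {
  fit_scope <- match.arg(fit_scope)
  part <- partitions(cs)
  fit_rows <- if (fit_scope == "train" && !is.null(part))
    which(part %in% c("train", "validation")) else seq_len(length(cs))
  states <- list()
  for (mod in c("descriptors", "ecfp4", "maccs")) {
    raw <- featureBlock(cs, mod)
    # the zero-variance filter applies to the descriptor panel; the
    # sparse fingerprints go to PCA with their full bit set
    if (mod == "descriptors") {
      m <- dropZeroVariance(raw, fit_rows)
      st <- list(kept = attr(m, "kept"))
    } else {
      m <- raw
      st <- list(kept = seq_len(ncol(raw)))
    }
    if (mod == "descriptors") {
      imp <- imputeNonFinite(m, fit_rows)
      st$medians <- imp$medians
      sc <- fitApplyStandardizer(imp$matrix, fit_rows)
      st$center1 <- sc$center; st$scale1 <- sc$scale
      m <- sc$matrix
    }
    pc <- pcaReduce(m, fit_rows, target_dim)
    st$pca_center <- pc$center; st$rotation <- pc$rotation
    st$explained_variance <- pc$explained_variance
    sc2 <- .standardize_tolerant(pc$matrix, fit_rows)
    st$center2 <- sc2$center; st$scale2 <- sc2$scale; st$dead <- sc2$dead
    featureBlock(cs, paste0(mod, ".", target_dim)) <- sc2$matrix
    states[[mod]] <- st
  }
  md <- metadata(cs)
  md$preprocess <- list(states = states, fit_scope = fit_scope,
                        target_dim = target_dim, fit_rows = fit_rows)
  metadata(cs) <- md
  cs
}

#' Transform new compounds with a fitted preprocessing state
#'
#' @param state One modality's entry of `metadata(cs)$preprocess$states`.
#' @param mat Raw feature matrix of the same modality for new compounds.
#' @return Processed `target_dim`-wide matrix.
#' @export
applyPreprocess <- function(state, mat) {
  m <- mat[, state$kept, drop = FALSE]
  if (!is.null(state$medians)) {
    bad <- !is.finite(m)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)
      m[bad] <- state$medians[idx[, 2]]
    }
    m <- applyStandardizer(m, state$center1, state$scale1)
  }
  m <- sweep(m, 2, state$pca_center) %*% state$rotation
  m <- applyStandardizer(m, state$center2, state$scale2)
  if (!is.null(state$dead)) m[, state$dead] <- 0
  m
}

#' The eight feature combinations
#'
#' Combination ids follow the study design: (1) descriptors, (2) ECFP4,
#' (3) MACCS, (4) SMILES tokens, (5) descriptors+ECFP4,
#' (6) descriptors+MACCS, (7) MACCS+ECFP4,
#' (8) descriptors+ECFP4+MACCS.
#'
#' @return Named list mapping combo id to modality names in their
#'   concatenation order.
#' @export
featureCombos <- function() {
  list(`1` = "descriptors", `2` = "ecfp4", `3` = "maccs", `4` = "smiles",
       `5` = c("descriptors", "ecfp4"), `6` = c("descriptors", "maccs"),
       `7` = c("maccs", "ecfp4"), `8` = c("descriptors", "ecfp4", "maccs"))
}

#' Fuse processed feature blocks (early fusion)
#'
#' Horizontally concatenates the processed 128-dimensional blocks of a
#' combination, recording the block boundaries so the constituents can be
#' recovered exactly.
#'
#' @param cs A [CompoundSet-class] after [preprocessFeatures()].
#' @param combo_id Integer 1-8 (see [featureCombos()]); combo 4 (SMILES)
#'   is a token encoding, not a numeric matrix, and is rejected here.
#' @param target_dim Width of each processed block (default 128).
#' @return A `FusedFeature`: list with `matrix`, `combo_id`, `blocks`,
#'   `boundaries` (named start indices).
#' @export
fuseBlocks <- function(cs, combo_id, target_dim = 128L) {
  combos <- featureCombos()
  key <- as.character(combo_id)
  if (!key %in% names(combos)) stop("unknown combo id: ", combo_id)
  mods <- combos[[key]]
  if (identical(mods, "smiles"))
    stop("combo 4 is the SMILES token encoding; use tokenizedSmiles()")
  parts <- lapply(mods, function(mod) {
    nm <- paste0(mod, ".", target_dim)
    b <- featureBlock(cs, nm)
    if (ncol(b) != target_dim)
      stop(sprintf("block %s has width %d, expected %d", nm, ncol(b), target_dim))
    b
  })
  mat <- do.call(cbind, parts)
  boundaries <- stats::setNames(seq(1L, by = target_dim, length.out = length(mods)),
                                mods)
  structure(list(matrix = mat, combo_id = combo_id, blocks = mods,
                 boundaries = boundaries),
            class = "FusedFeature")
}

#' Recover the constituent blocks of a fused feature
#'
#' @param fused A `FusedFeature` from [fuseBlocks()].
#' @return Named list of the constituent matrices.
#' @export
splitFused <- function(fused) {
  w <- diff(c(unname(fused$boundaries), ncol(fused$matrix) + 1L))
  out <- Map(function(start, width) {
    fused$matrix[, start:(start + width - 1L), drop = FALSE]
  }, fused$boundaries, w)
  stats::setNames(out, fused$blocks)
}
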