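#' Synthetic minority oversampling (SMOTE)
#'
#' Generates synthetic minority-class rows by linear interpolation: each
#' new row is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)` and `x_nn`
#' one of the `k_neighbors` nearest minority neighbours of a randomly
#' chosen minority row `x_i` (Euclidean distance).
#'
#' @param minority_rows Numeric matrix of minority-class feature rows.
#' @param n_new Number of synthetic rows to generate.
#' @param k_neighbors Neighbourhood size (default 5).
#' @param seed Integer seed.
#' @return List with `rows` (n_new x d matrix) and `records`
#'   (data.frame: `parent`, `neighbor`, `u` per synthetic row).
#' @export
smote <- function(minority_rows, n_new, k_neighbors = 5L, seed = 1L) {
  n <- nrow(minority_rows)
  if (n < k_neighbors + 1L)
    stop(sprintf("minority size %d too small for k=%d; use k <= %d",
                 n, k_neighbors, n - 1L))
  stopifnot(n_new >= 1L)
  d2 <- sqDistMatrix(minority_rows)
  diag(d2) <- Inf
  ord <- apply(d2, 1, function(row) order(row)[seq_len(k_neighbors)])
  nn <- t(matrix(ord, nrow = k_neighbors))  # n x k, robust to k = 1
  withSeed(seed, {
    parent <- sample.int(n, n_new, replace = TRUE)
    pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    u <- stats::runif(n_new)
  })
  neighbor <- nn[cbind(parent, pick)]
  rows <- minority_rows[parent, , drop = FALSE] +
    u * (minority_rows[neighbor, , drop = FALSE] -
           minority_rows[parent, , drop = FALSE])
  list(rows = rows,
       records = data.frame(parent = parent, neighbor = neighbor, u = u))
}

#' Enumerate alternative SMILES notations
#'
#' Generates randomized (atom-renumbered) SMILES variants of each input
#' molecule; every variant denotes the same molecule and canonicalizes
#' back to the input. Variants are deduplicated under a retry cap, so
#' molecules with few distinct notations may return fewer than
#' `n_variants` (reported).
#'
#' @param smiles Character vector of valid SMILES.
#' @param n_variants Variants requested per molecule.
#' @param seed Integer seed.
#' @return List of character vectors, one per input molecule.
#' @export
enumerateSmiles <- function(smiles, n_variants, seed = 1L) {
  stopifnot(n_variants >= 1L)
  out <- .rdkit("enum", smiles, c(as.character(n_variants), as.character(seed)))
  bad <- .rdkit_errors(out)
  if (any(bad)) stop("invalid SMILES: ", paste(smiles[bad], collapse = ", "))
  variants <- strsplit(out, "\t", fixed = TRUE)
  short <- lengths(variants) < n_variants
  if (any(short))
    message(sum(short), " molecule(s) returned fewer than ", n_variants,
            " distinct notations")
  variants
}

#' Decoy selection criteria
#'
#' Property-matching windows (DUD-E-style), maximum allowed ECFP4 Tanimoto
#' similarity to any active, and the requested decoy count.
#'
#' @param mw,logp,hbd,hba,rotb Matching half-windows for molecular weight
#'   (Da), logP, H-bond donors/acceptors and rotatable bonds.
#' @param charge_exact Require identical net charge (default TRUE).
#' @param max_tanimoto Maximum ECFP4 Tanimoto to any active (in (0,1)).
#' @param count Number of decoys requested.
#' @return A `DecoyCriteria` list.
#' @export
decoyCriteria <- function(mw = 25, logp = 1.0, hbd = 1, hba = 2, rotb = 2,
                          charge_exact = TRUE, max_tanimoto = 0.30,
                          count = 100L) {
  stopifnot(mw >= 0, logp >= 0, hbd >= 0, hba >= 0, rotb >= 0,
            max_tanimoto > 0, max_tanimoto < 1, count >= 1L)
  structure(list(mw = mw, logp = logp, hbd = hbd, hba = hba, rotb = rotb,
                 charge_exact = charge_exact, max_tanimoto = max_tanimoto,
                 count = as.integer(count)),
            class = "DecoyCriteria")
}

# Physicochemical property panel used for decoy matching.
.decoy_props <- function(smiles) {
  out <- .rdkit("props", smiles)
  bad <- .rdkit_errors(out)
  if (any(bad)) stop("invalid SMILES in property panel: ",
                     paste(smiles[bad], collapse = ", "))
  m <- .tsv_to_matrix(out, 6L)
  colnames(m) <- c("mw", "logp", "hbd", "hba", "rotb", "charge")
  m
}

# Tanimoto similarity between rows of two binary matrices.
.tanimoto <- function(a, b) {
  inter <- tcrossprod(a, b)
  ra <- rowSums(a); rb <- rowSums(b)
  un <- outer(ra, rb, "+") - inter
  s <- inter / un
  s[un == 0] <- 1  # two empty fingerprints are identical
  s
}

#' Select unbiased decoy compounds
#'
#' Three-stage funnel: (1) property matching - a candidate passes when
#' each panel property (MW, logP, HBD, HBA, rotatable bonds; net charge
#' exactly if required) lies within the window of at least one active;
#' (2) structural dissimilarity - its maximum ECFP4 Tanimoto to every
#' active is below the threshold; (3) diversity - MaxMin selection on
#' Tanimoto distance down to the requested count (seeded, starting from
#' the most distant survivor pair).
#'
#' @param actives Character vector of active canonical SMILES.
#' @param pool Character vector of candidate decoy SMILES.
#' @param criteria A [decoyCriteria()].
#' @param seed Integer seed (tie-breaking).
#' @return List with `decoys` (selected SMILES), `funnel` (per-stage
#'   survivor counts) and `records` (data.frame of selected decoys).
#' @export
selectDecoys <- function(actives, pool, criteria = decoyCriteria(),
                         seed = 1L) {
  if (!length(pool)) stop("empty decoy pool")
  stopifnot(inherits(criteria, "DecoyCriteria"))
  pa <- .decoy_props(actives)
  pp <- .decoy_props(pool)
  win <- c(mw = criteria$mw, logp = criteria$logp, hbd = criteria$hbd,
           hba = criteria$hba, rotb = criteria$rotb)
  prop_ok <- rep(TRUE, length(pool))
  for (p in names(win)) {
    lo <- min(pa[, p]) - win[[p]]; hi <- max(pa[, p]) + win[[p]]
    # within the window of at least one active <=> within the padded range
    near <- vapply(pp[, p], function(v) any(abs(v - pa[, p]) <= win[[p]]), NA)
    prop_ok <- prop_ok & near & pp[, p] >= lo & pp[, p] <= hi
  }
  if (criteria$charge_exact)
    prop_ok <- prop_ok & pp[, "charge"] %in% pa[, "charge"]
  survivors1 <- which(prop_ok)
  funnel <- data.frame(stage = "property_match", survivors = length(survivors1))
  if (!length(survivors1))
    return(list(decoys = character(), funnel = funnel,
                records = data.frame()))
  fa <- .bits_to_matrix(.rdkit("fp", actives, "ecfp4"))
  fp <- .bits_to_matrix(.rdkit("fp", pool[survivors1], "ecfp4"))
  max_sim <- apply(.tanimoto(fp, fa), 1, max)
  survivors2 <- survivors1[max_sim < criteria$max_tanimoto]
  funnel <- rbind(funnel, data.frame(stage = "dissimilarity",
                                     survivors = length(survivors2)))
  if (length(survivors2) < criteria$count) {
    warning(sprintf("only %d decoys survive the filters (requested %d)",
                    length(survivors2), criteria$count))
    sel <- survivors2
  } else {
    fs <- fp[match(survivors2, survivors1), , drop = FALSE]
    sel <- survivors2[.maxmin_select(fs, criteria$count, seed)]
  }
  funnel <- rbind(funnel, data.frame(stage = "diversity",
                                     survivors = length(sel)))
  list(decoys = pool[sel], funnel = funnel,
       records = data.frame(smiles = pool[sel], pool_index = sel))
}

# MaxMin diversity pick on Tanimoto distance (1 - similarity): start with
# the most distant pair, then greedily add the candidate whose minimum
# distance to the selection is largest.
.maxmin_select <- function(fps, count, seed = 1L) {
  n <- nrow(fps)
  if (count >= n) return(seq_len(n))
  d <- 1 - .tanimoto(fps, fps)
  if (count == 1L) return(withSeed(seed, sample.int(n, 1L)))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  sel <- as.integer(far)
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < count) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  sel
}

#' Re-check selected decoys against their own criteria
#'
#' @param decoys Selected decoy SMILES.
#' @param actives Active SMILES they were selected against.
#' @param criteria The [decoyCriteria()] used.
#' @return Logical vector, `TRUE` where the decoy satisfies the criteria.
#' @export
decoysSatisfy <- function(decoys, actives, criteria) {
  if (!length(decoys)) return(logical())
  pa <- .decoy_props(actives); pd <- .decoy_props(decoys)
  win <- c(mw = criteria$mw, logp = criteria$logp, hbd = criteria$hbd,
           hba = criteria$hba, rotb = criteria$rotb)
  ok <- rep(TRUE, length(decoys))
  for (p in names(win))
    ok <- ok & vapply(pd[, p], function(v)
      any(abs(v - pa[, p]) <= win[[p]]), NA)
  if (criteria$charge_exact) ok <- ok & pd[, "charge"] %in% pa[, "charge"]
  fa <- .bits_to_matrix(.rdkit("fp", actives, "ecfp4"))
  fd <- .bits_to_matrix(.rdkit("fp", decoys, "ecfp4"))
  ok & apply(.tanimoto(fd, fa), 1, max) < criteria$max_tanimoto
}
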