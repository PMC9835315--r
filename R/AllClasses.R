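#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

#' CompoundSet: curated compounds with multimodal features
#'
#' The central container of the package. It holds one row per unique
#' curated compound (canonical SMILES), per-compound metadata (potency in
#' micromolar, binary activity label, cutoff, provenance counts, cluster
#' and partition assignments), the multimodal feature blocks (descriptor,
#' MACCS and ECFP4 matrices, compounds in rows), and an optional tokenized
#' SMILES encoding.
#'
#' Feature blocks of the three numeric modalities have different widths,
#' so they live in a named [S4Vectors::SimpleList] of matrices rather than
#' the equal-dimension assays of a SummarizedExperiment; row counts must
#' all equal the number of compounds.
#'
#' @slot compoundData A [S4Vectors::DataFrame] with at least
#'   `canonical_smiles`; curation adds `activity_um`, `label`, `cutoff_um`,
#'   `n_merged`; splitting adds `cluster` and `partition`.
#' @slot featureBlocks Named [S4Vectors::SimpleList] of numeric matrices,
#'   one row per compound.
#' @slot tokens A list with elements `vocabulary`, `sequences`, `lengths`
#'   (or empty before [encodeSmiles()]).
#' @aliases CompoundSet-class
#' @export
setClass("CompoundSet",
  representation(compoundData = "DataFrame",
                 featureBlocks = "SimpleList",
                 tokens = "list",
                 metadata = "list"),
  prototype(compoundData = S4Vectors::DataFrame(canonical_smiles = character()),
            featureBlocks = S4Vectors::SimpleList(),
            tokens = list(),
            metadata = list()))

#' @describeIn CompoundSet-class Free-form metadata (preprocessing states,
#'   split reports, ground-truth manifests).
#' @param x A `CompoundSet`.
#' @export
setMethod("metadata", "CompoundSet", function(x) x@metadata)

#' @describeIn CompoundSet-class Replace metadata.
#' @param value A list.
#' @export
setReplaceMethod("metadata", "CompoundSet", function(x, value) {
  x@metadata <- value; x
})

setValidity("CompoundSet", function(object) {
  cd <- object@compoundData
  msg <- character()
  if (!"canonical_smiles" %in% colnames(cd))
    msg <- c(msg, "compoundData must contain 'canonical_smiles'")
  else if (anyDuplicated(cd$canonical_smiles))
    msg <- c(msg, "canonical_smiles must be unique within a CompoundSet")
  if ("activity_um" %in% colnames(cd) && any(cd$activity_um <= 0))
    msg <- c(msg, "activity_um must be positive")
  if ("label" %in% colnames(cd) && !all(cd$label %in% c(0L, 1L)))
    msg <- c(msg, "label must be 0/1")
  n <- nrow(cd)
  bad <- vapply(object@featureBlocks, function(m) nrow(m) != n, logical(1))
  if (any(bad))
    msg <- c(msg, sprintf("feature block(s) %s have wrong row count",
                          paste(names(object@featureBlocks)[bad], collapse = ", ")))
  if (length(object@tokens) && nrow(object@tokens$sequences) != n)
    msg <- c(msg, "token sequence matrix has wrong row count")
  if (length(msg)) msg else TRUE
})

#' Construct a CompoundSet
#'
#' @param canonical_smiles Character vector of unique canonical SMILES.
#' @param ... Further per-compound columns (e.g. `activity_um`, `label`).
#' @return A [CompoundSet-class] object.
#' @examples
#' cs <- CompoundSet(c("CCO", "c1ccccc1"), activity_um = c(0.2, 30))
#' @export
CompoundSet <- function(canonical_smiles, ...) {
  new("CompoundSet",
      compoundData = S4Vectors::DataFrame(canonical_smiles = canonical_smiles, ...),
      featureBlocks = S4Vectors::SimpleList(),
      tokens = list())
}

#' @describeIn CompoundSet-class Number of compounds.
#' @param x A `CompoundSet`.
#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@compoundData))

setMethod("show", "CompoundSet", function(object) {
  cd <- object@compoundData
  cat("CompoundSet with", nrow(cd), "compounds\n")
  if ("label" %in% colnames(cd))
    cat(sprintf("  labels: %d active / %d inactive (cutoff %s uM)\n",
                sum(cd$label == 1L), sum(cd$label == 0L),
                paste(unique(cd$cutoff_um), collapse = ",")))
  if (length(object@featureBlocks))
    cat("  feature blocks:",
        paste(sprintf("%s[%d]", names(object@featureBlocks),
                      vapply(object@featureBlocks, ncol, 0L)), collapse = ", "),
        "\n")
  if (length(object@tokens))
    cat(sprintf("  tokens: max_len %d, vocabulary %d symbols\n",
                ncol(object@tokens$sequences), length(object@tokens$vocabulary)))
  if ("partition" %in% colnames(cd))
    cat("  partitions:",
        paste(names(table(cd$partition)), table(cd$partition),
              sep = "=", collapse = ", "), "\n")
})

#' Subset a CompoundSet by compound
#'
#' Subsets metadata, every feature block and the token matrix coherently.
#'
#' @param x A `CompoundSet`.
#' @param i Row (compound) index.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  x@compoundData <- x@compoundData[i, , drop = FALSE]
  x@featureBlocks <- S4Vectors::SimpleList(
    lapply(x@featureBlocks, function(m) m[i, , drop = FALSE]))
  if (length(x@tokens)) {
    x@tokens$sequences <- x@tokens$sequences[i, , drop = FALSE]
    x@tokens$lengths <- x@tokens$lengths[i]
  }
  validObject(x)
  x
})
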