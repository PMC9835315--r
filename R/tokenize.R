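#' Tokenize SMILES strings
#'
#' Splits a SMILES into chemically meaningful symbols: bracket atoms
#' (`[nH]`, `[O-]`, ...) and the two-letter elements `Cl`/`Br` are single
#' tokens, as are two-digit ring closures (`%10`); everything else is one
#' character. A character-level mode is available.
#'
#' @param smiles Character vector.
#' @param mode `"symbol"` (default) or `"character"`.
#' @return List of character vectors, one per input.
#' @examples
#' tokenizeSmiles("CCCl")[[1]]  # "C" "C" "Cl"
#' @export
tokenizeSmiles <- function(smiles, mode = c("symbol", "character")) {
  mode <- match.arg(mode)
  if (mode == "character") return(strsplit(smiles, ""))
  pattern <- "\\[[^\\]]+\\]|Cl|Br|%[0-9]{2}|."
  regmatches(smiles, gregexpr(pattern, smiles, perl = TRUE))
}

#' Build a SMILES token vocabulary
#'
#' Deterministic (sorted) mapping of every symbol occurring in the corpus
#' to a positive integer id; id 0 is reserved for padding.
#'
#' @param smiles Character vector (the corpus).
#' @param mode Tokenization mode, see [tokenizeSmiles()].
#' @param extra_symbols Symbols to include even if absent from the corpus.
#' @return Named integer vector: `c("<pad>" = 0L, symbol = id, ...)`.
#' @export
buildVocabulary <- function(smiles, mode = "symbol",
                            extra_symbols = character()) {
  stopifnot(length(smiles) > 0L)
  syms <- sort(unique(c(unlist(tokenizeSmiles(smiles, mode)), extra_symbols)),
               method = "radix")
  stats::setNames(c(0L, seq_along(syms)), c("<pad>", syms))
}

#' Encode SMILES as padded integer sequences
#'
#' Each SMILES becomes a row of token ids, zero-padded on the right to
#' `max_len`. Symbols absent from the vocabulary or sequences longer than
#' `max_len` are hard errors (no silent truncation).
#'
#' @param smiles Character vector.
#' @param vocabulary From [buildVocabulary()].
#' @param max_len Maximum token length (default 195).
#' @param mode Tokenization mode.
#' @return List with `sequences` (n x max_len integer matrix), `lengths`,
#'   `vocabulary`.
#' @export
encodeSmiles <- function(smiles, vocabulary, max_len = 195L,
                         mode = "symbol") {
  toks <- tokenizeSmiles(smiles, mode)
  lens <- lengths(toks)
  if (any(lens > max_len))
    stop(sprintf("%d SMILES exceed max_len %d (longest: %d tokens)",
                 sum(lens > max_len), max_len, max(lens)))
  unknown <- setdiff(unique(unlist(toks)), names(vocabulary))
  if (length(unknown))
    stop("symbols not in vocabulary: ", paste(unknown, collapse = " "))
  seqs <- matrix(0L, length(smiles), max_len)
  for (i in seq_along(toks)) {
    if (lens[i]) seqs[i, seq_len(lens[i])] <- vocabulary[toks[[i]]]
  }
  list(sequences = seqs, lengths = lens, vocabulary = vocabulary)
}

#' Decode token ids back to symbols
#'
#' @param ids Integer vector (one sequence; trailing zeros are padding).
#' @param vocabulary From [buildVocabulary()].
#' @return Character vector of symbols.
#' @export
decodeTokens <- function(ids, vocabulary) {
  ids <- ids[ids != 0L]
  names(vocabulary)[match(ids, vocabulary)]
}

#' Attach a tokenized-SMILES encoding to a CompoundSet
#'
#' @param cs A [CompoundSet-class].
#' @param vocabulary Optional prebuilt vocabulary (default: built from the
#'   set's own SMILES).
#' @param max_len Maximum token length.
#' @return `cs` with `tokenizedSmiles(cs)` populated.
#' @export
encodeCompoundSet <- function(cs, vocabulary = NULL, max_len = 195L) {
  smi <- canonicalSmiles(cs)
  if (is.null(vocabulary)) vocabulary <- buildVocabulary(smi)
  tokenizedSmiles(cs) <- encodeSmiles(smi, vocabulary, max_len)
  cs
}
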