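#' Read an activity table into activity records
#'
#' Reads a delimited text file of assay results (one row per measurement)
#' and maps its columns onto the fields of an activity record: SMILES,
#' assay type (Ki, Kd or IC50), numeric potency value and unit. Rows with
#' an unparseable value, a unit outside nM/uM/mM, an unknown assay type or
#' an empty SMILES are skipped and reported.
#'
#' @param path Path to a CSV/TSV file.
#' @param columns Named character vector mapping record fields to column
#'   names, with names `smiles`, `assay_type`, `value`, `unit` and
#'   optionally `source_id`.
#' @param sep Field separator; guessed from the file extension by default.
#' @return A `data.frame` of records (`smiles_raw`, `assay_type`, `value`,
#'   `unit`, `source_id`) with attribute `rejected` describing skipped rows.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("smi,type,val,u", "CCO,IC50,500,nM"), f)
#' parseActivityTable(f, c(smiles = "smi", assay_type = "type",
#'                         value = "val", unit = "u"))
#' @export
parseActivityTable <- function(path,
                               columns = c(smiles = "smiles",
                                           assay_type = "assay_type",
                                           value = "value", unit = "unit"),
                               sep = NULL) {
  if (!file.exists(path)) stop("activity table not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0L) {
    warning("empty activity table: ", path)
    return(structure(data.frame(smiles_raw = character(),
                                assay_type = character(),
                                value = numeric(), unit = character(),
                                source_id = character()),
                     rejected = data.frame()))
  }
  need <- c("smiles", "assay_type", "value", "unit")
  missing_cols <- setdiff(columns[need], colnames(df))
  if (length(missing_cols))
    stop("mapped columns absent from table: ", paste(missing_cols, collapse = ", "))
  rec <- data.frame(
    smiles_raw = trimws(as.character(df[[columns[["smiles"]]]])),
    assay_type = trimws(as.character(df[[columns[["assay_type"]]]])),
    value = suppressWarnings(as.numeric(df[[columns[["value"]]]])),
    unit = trimws(as.character(df[[columns[["unit"]]]])),
    source_id = if ("source_id" %in% names(columns) &&
                    columns[["source_id"]] %in% colnames(df))
      as.character(df[[columns[["source_id"]]]]) else as.character(seq_len(nrow(df))),
    stringsAsFactors = FALSE)
  # unit spellings: ASCII and Greek mu both accepted
  rec$unit <- sub("^[uµμ]M$", "uM", rec$unit)
  ok_unit <- rec$unit %in% c("nM", "uM", "mM")
  ok_val <- is.finite(rec$value) & rec$value > 0
  ok_assay <- toupper(rec$assay_type) %in% c("KI", "KD", "IC50")
  ok_smi <- nzchar(rec$smiles_raw)
  keep <- ok_unit & ok_val & ok_assay & ok_smi
  rejected <- rec[!keep, , drop = FALSE]
  rejected$reason <- ifelse(!ok_smi[!keep], "empty SMILES",
                     ifelse(!ok_val[!keep], "unparseable or non-positive value",
                     ifelse(!ok_unit[!keep], "unknown unit", "unknown assay type")))
  if (nrow(rejected))
    message(nrow(rejected), " record(s) rejected during parsing")
  structure(rec[keep, , drop = FALSE], rejected = rejected)
}

#' Convert a potency value to micromolar
#'
#' @param value Positive numeric vector of potencies.
#' @param unit Character vector of units, each one of `"nM"`, `"uM"`,
#'   `"mM"` (the Greek-mu spelling is accepted).
#' @return Potency in micromolar.
#' @examples
#' convertToMicromolar(500, "nM")   # 0.5
#' convertToMicromolar(0.002, "mM") # 2
#' @export
convertToMicromolar <- function(value, unit) {
  stopifnot(length(value) == length(unit) || length(unit) == 1L)
  unit <- sub("^[uµμ]M$", "uM", unit)
  factor <- c(nM = 1e-3, uM = 1, mM = 1e3)[unit]
  if (anyNA(factor))
    stop("unknown unit(s): ", paste(unique(unit[is.na(factor)]), collapse = ", "))
  unname(value * factor)
}

#' Canonicalize SMILES strings
#'
#' Maps each SMILES to the toolkit-canonical form, so that any two
#' notations of the same molecule become identical strings.
#'
#' @param smiles Character vector of SMILES.
#' @param on_error `"stop"` (default) to fail on the first invalid SMILES,
#'   or `"na"` to return `NA` for invalid entries (callers then drop and
#'   report them).
#' @return Character vector of canonical SMILES.
#' @examples \dontrun{
#' canonicalizeSmiles(c("C1=CC=CC=C1", "c1ccccc1"))  # identical outputs
#' }
#' @export
canonicalizeSmiles <- function(smiles, on_error = c("stop", "na")) {
  on_error <- match.arg(on_error)
  if (!length(smiles)) return(character())
  out <- .rdkit("canon", smiles)
  bad <- .rdkit_errors(out)
  if (any(bad)) {
    if (on_error == "stop")
      stop("invalid SMILES: ", paste(utils::head(smiles[bad], 5), collapse = ", "))
    out[bad] <- NA_character_
  }
  out
}

#' Aggregate duplicate measurements into unique compounds
#'
#' Collapses records sharing a canonical SMILES into one entry whose
#' potency is the median of the member potencies (robust to the odd
#' discordant assay); the number of merged records is kept for audit.
#'
#' @param canonical_smiles Character vector (already canonical).
#' @param activity_um Numeric potencies in micromolar.
#' @return A `data.frame` with columns `canonical_smiles`, `activity_um`,
#'   `n_merged`, one row per unique compound, in first-appearance order.
#' @examples
#' aggregateDuplicates(c("CCO", "CCO"), c(0.4, 0.6))  # activity_um 0.5
#' @export
aggregateDuplicates <- function(canonical_smiles, activity_um) {
  stopifnot(length(canonical_smiles) == length(activity_um),
            all(activity_um > 0))
  idx <- split(seq_along(canonical_smiles), canonical_smiles)
  idx <- idx[order(vapply(idx, min, 0L))]  # first-appearance order
  data.frame(
    canonical_smiles = names(idx),
    activity_um = vapply(idx, function(i) stats::median(activity_um[i]), 0),
    n_merged = lengths(idx),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign binary activity labels at a potency cutoff
#'
#' A compound is labeled active (1) when its potency is strictly less than
#' the cutoff; potency equal to the cutoff is inactive (0).
#'
#' @param compounds `data.frame` with `canonical_smiles`, `activity_um`
#'   and optionally `n_merged` (as from [aggregateDuplicates()]).
#' @param cutoff_um Activity cutoff in micromolar; the study design uses
#'   0.5, 1 or 10 (other values are allowed with a warning).
#' @return A [CompoundSet-class] with `label` and `cutoff_um` columns.
#' @examples
#' cmp <- data.frame(canonical_smiles = c("CCO", "CCN"),
#'                   activity_um = c(0.4, 12))
#' assignLabels(cmp, 10)
#' @export
assignLabels <- function(compounds, cutoff_um) {
  stopifnot(is.numeric(cutoff_um), length(cutoff_um) == 1L, cutoff_um > 0)
  if (!cutoff_um %in% c(0.5, 1, 10))
    warning("cutoff ", cutoff_um, " uM is outside the standard set {0.5, 1, 10}")
  label <- as.integer(compounds$activity_um < cutoff_um)
  cs <- CompoundSet(compounds$canonical_smiles,
                    activity_um = compounds$activity_um,
                    label = label,
                    cutoff_um = cutoff_um,
                    n_merged = if (is.null(compounds$n_merged))
                      rep(1L, nrow(compounds)) else compounds$n_merged)
  message(sprintf("labels at %g uM: %d active, %d inactive",
                  cutoff_um, sum(label == 1L), sum(label == 0L)))
  cs
}

#' Curate raw activity records into a labeled compound set
#'
#' Full curation: canonicalize SMILES (dropping and reporting invalid
#' ones), convert potencies to micromolar, aggregate duplicates by median,
#' and label at the cutoff.
#'
#' @param records Records as returned by [parseActivityTable()].
#' @param cutoff_um Activity cutoff in micromolar.
#' @return A [CompoundSet-class].
#' @export
curateCompounds <- function(records, cutoff_um) {
  canon <- canonicalizeSmiles(records$smiles_raw, on_error = "na")
  if (anyNA(canon))
    message(sum(is.na(canon)), " record(s) dropped: failed canonicalization")
  keep <- !is.na(canon)
  um <- convertToMicromolar(records$value[keep], records$unit[keep])
  agg <- aggregateDuplicates(canon[keep], um)
  assignLabels(agg, cutoff_um)
}

#' Read activity records from an SDF file
#'
#' Reads molecules and activity properties from an SDF datablock via the
#' ChemmineR package (required only for this reader).
#'
#' @param path SDF file path.
#' @param fields Named character vector mapping `assay_type`, `value`,
#'   `unit` to datablock property names.
#' @return A `data.frame` in the layout of [parseActivityTable()].
#' @export
readSdfActivities <- function(path,
                              fields = c(assay_type = "assay_type",
                                         value = "value", unit = "unit")) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("readSdfActivities requires the ChemmineR package")
  sdf <- ChemmineR::read.SDFset(path)
  db <- ChemmineR::datablock(sdf)
  rec <- do.call(rbind, lapply(seq_along(db), function(i) {
    d <- db[[i]]
    data.frame(smiles_raw = as.character(ChemmineR::sdf2smiles(sdf[i])),
               assay_type = d[[fields[["assay_type"]]]],
               value = as.numeric(d[[fields[["value"]]]]),
               unit = d[[fields[["unit"]]]],
               source_id = ChemmineR::sdfid(sdf[i]),
               stringsAsFactors = FALSE)
  }))
  rec
}

#' Write / read the curated compound table
#'
#' The curated CSV schema is `canonical_smiles, activity_um, label,
#' cutoff_um, n_merged` (plus any extra columns present, e.g. `family`).
#'
#' @param cs A [CompoundSet-class].
#' @param path Output CSV path.
#' @return `writeCuratedCsv` returns `path` invisibly; `readCuratedCsv`
#'   returns a [CompoundSet-class].
#' @export
writeCuratedCsv <- function(cs, path) {
  utils::write.csv(as.data.frame(compoundData(cs)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCuratedCsv
#' @export
readCuratedCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  do.call(CompoundSet, df)
}
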