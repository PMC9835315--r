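#' @importFrom utils head tail read.csv write.csv
NULL

.python_bin <- function() getOption("chemfusion.python", "python")

.rdkit_script <- function() {
  p <- system.file("python", "rdkit_tools.py", package = "ChemFusion")
  if (!nzchar(p)) stop("rdkit_tools.py not found in installed package")
  p
}

#' Check that the RDKit chemistry backend is available
#'
#' ChemFusion delegates chemistry primitives (canonicalization, descriptors,
#' fingerprints, SMILES enumeration) to the RDKit toolkit through the
#' `python` interpreter on the PATH.
#'
#' @return `TRUE` invisibly if the backend responds; otherwise an error.
#' @export
checkChemBackend <- function() {
  out <- tryCatch(.rdkit("canon", "CCO"), error = function(e) e)
  if (inherits(out, "error") || !identical(out, "CCO"))
    stop("RDKit backend unavailable: need `python` with rdkit importable")
  invisible(TRUE)
}

# Run one batched backend call; returns one output line per input line.
.rdkit <- function(cmd, smiles, args = character()) {
  infile <- tempfile("smi"); outfile <- tempfile("out")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(smiles, infile)
  status <- system2(.python_bin(),
                    c(shQuote(.rdkit_script()), cmd, shQuote(infile), args),
                    stdout = outfile, stderr = FALSE)
  if (!identical(status, 0L))
    stop(sprintf("RDKit backend call '%s' failed (exit %d)", cmd, status))
  out <- readLines(outfile)
  if (length(out) != length(smiles))
    stop("RDKit backend returned wrong number of lines")
  out
}

.rdkit_errors <- function(out) startsWith(out, "ERROR\t")

# Parse equal-width 0/1 strings into an integer matrix (rows = compounds).
.bits_to_matrix <- function(bits) {
  stopifnot(length(unique(nchar(bits))) == 1L)
  raw <- charToRaw(paste(bits, collapse = ""))
  matrix(as.integer(raw == charToRaw("1")),
         nrow = length(bits), byrow = TRUE)
}

# Parse tab-separated numeric lines into a matrix.
.tsv_to_matrix <- function(lines, ncol) {
  vals <- scan(text = gsub("\t", " ", lines), what = numeric(),
               quiet = TRUE, na.strings = c("nan", "inf", "-inf"))
  matrix(vals, nrow = length(lines), ncol = ncol, byrow = TRUE)
}
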