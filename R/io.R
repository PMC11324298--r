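# File I/O: FASTA (via Biostrings), substitution matrices, and the TSV
# table formats used across the pipeline.

#' Read protein or peptide sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write sequences to FASTA
#'
#' Output is byte-deterministic for a given input (fixed 60-column wrap).
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a substitution matrix in square text layout
#'
#' Expects a header row of residue letters and one labelled row per residue.
#'
#' @param path Matrix file path.
#' @return Numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    as_error("substitution matrix must be square with matching row/column labels")
  }
  storage.mode(m) <- "double"
  m
}

#' The shipped BLOSUM62 matrix
#'
#' The published BLOSUM62 substitution matrix over the 20 canonical residues,
#' shipped as a constant data file and used for template selection.
#'
#' @return 20 x 20 numeric matrix.
#' @export
blosum62 <- function() {
  read_substitution_matrix(system.file("extdata", "blosum62.tsv",
                                       package = "adductscan", mustWork = TRUE))
}

#' Read an epitope list
#'
#' TSV with columns `sequence`, `ic50_nm`, `allele`.
#'
#' @param path File path.
#' @return Data frame of epitope records.
#' @export
read_epitope_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "ic50_nm", "allele")
  if (!all(need %in% names(df))) {
    as_error("epitope table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(!is.na(df$ic50_nm) & df$ic50_nm <= 0)) {
    as_error("ic50_nm values must be positive where present")
  }
  df
}

#' Read a tissue expression table
#'
#' TSV with columns `protein`, `tissue`, `expression` (nonnegative, one
#' consistent unit across the table); `(protein, tissue)` pairs unique.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "tissue", "expression")
  if (!all(need %in% names(df))) {
    as_error("expression table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$expression < 0)) as_error("expression levels must be >= 0")
  if (anyDuplicated(df[c("protein", "tissue")])) {
    as_error("(protein, tissue) pairs must be unique in the expression table")
  }
  df
}

#' Read an ortholog map
#'
#' TSV with columns `from`, `to` (e.g. human protein id to mouse homolog id).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(df))) {
    as_error("ortholog table must have columns: from, to")
  }
  df
}

#' Read an HLA allele phenotype-frequency table
#'
#' TSV with columns `population`, `allele`, `frequency` (phenotype frequency
#' in \[0,1\]); `(population, allele)` pairs unique.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_allele_freq_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "allele", "frequency")
  if (!all(need %in% names(df))) {
    as_error("allele frequency table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$frequency < 0 | df$frequency > 1)) {
    as_error("phenotype frequencies must lie in [0, 1]")
  }
  if (anyDuplicated(df[c("population", "allele")])) {
    as_error("(population, allele) pairs must be unique")
  }
  df
}

# Deterministic TSV writer (fixed numeric formatting, no quoting).
write_tsv_plain <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  out <- df
  out[is_num] <- lapply(df[is_num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
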