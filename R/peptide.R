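# Peptide sequence model with optional lysine adduct modifications.
# Positions are 1-based throughout (immunology P1...P9 convention).

#' Parse and validate a peptide sequence
#'
#' Builds a `peptide` object from a one-letter amino-acid string. Only the 20
#' canonical residue codes are accepted; any other character is a validation
#' error naming the offending 1-based position. N-terminal acetylation is a
#' peptide-level flag (it is applied uniformly during synthesis to block
#' N-terminal adduction), not a positional modification.
#'
#' @param text Amino-acid sequence, e.g. `"LAGKNLTHI"`.
#' @param acetylated Logical; is the peptide N-terminally acetylated?
#' @return An object of class `peptide` with fields `sequence`,
#'   `n_terminal_acetyl` and `modifications` (a named list mapping 1-based
#'   position to adduct species name).
#' @examples
#' p <- parse_peptide("LAGKNLTHI")
#' lysine_positions(p)  # 4
#' @seealso [apply_adduct()], [lysine_positions()]
#' @export
parse_peptide <- function(text, acetylated = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) as_error("peptide sequence must be non-empty")
  chars <- strsplit(toupper(text), "")[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0) {
    as_error("invalid residue '%s' at position %d: not a canonical amino-acid code",
             chars[bad[1]], bad[1])
  }
  structure(
    list(sequence = paste(chars, collapse = ""),
         n_terminal_acetyl = isTRUE(acetylated),
         modifications = list()),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(format_peptide(x), "\n", sep = "")
  invisible(x)
}

#' @export
length.peptide <- function(x) nchar(x$sequence)

#' 1-based positions of lysine residues in a peptide
#'
#' @param p A `peptide`.
#' @return Integer vector of positions carrying `K` (possibly empty).
#' @export
lysine_positions <- function(p) {
  stopifnot(inherits(p, "peptide"))
  which(strsplit(p$sequence, "")[[1]] == "K")
}

#' Record a lysine adduct on a peptide
#'
#' Returns a new peptide with the adduct species recorded at `pos`; the input
#' is unchanged. The target residue must be a lysine and must not already be
#' modified (at most one adduct per position).
#'
#' @param p A `peptide`.
#' @param pos 1-based residue position; must be a `K`.
#' @param species An `adduct_species` object or a species name string.
#' @return A modified copy of `p`.
#' @export
apply_adduct <- function(p, pos, species) {
  stopifnot(inherits(p, "peptide"))
  name <- if (inherits(species, "adduct_species")) species$name else as.character(species)
  pos <- as.integer(pos)
  n <- nchar(p$sequence)
  if (pos < 1 || pos > n) as_error("position %d outside peptide [1, %d]", pos, n)
  res <- substr(p$sequence, pos, pos)
  if (res != "K") {
    as_error("residue '%s' at position %d is not a lysine; adducts target K only", res, pos)
  }
  key <- as.character(pos)
  if (!is.null(p$modifications[[key]])) {
    as_error("position %d already carries modification '%s'", pos, p$modifications[[key]])
  }
  p$modifications[[key]] <- name
  p
}

#' Query the modification at a position
#'
#' @param p A `peptide`.
#' @param pos 1-based position.
#' @return The species name, or `NULL` if unmodified.
#' @export
modification_at <- function(p, pos) {
  stopifnot(inherits(p, "peptide"))
  p$modifications[[as.character(pos)]]
}

#' Serialize a peptide to text
#'
#' Format: optional `Ac-` prefix, the sequence, then `+species@pos` suffixes
#' in ascending position order, e.g. `"Ac-LAGKNLTHI+pyrrole@4"`. The format
#' round-trips exactly through [parse_peptide_text()].
#'
#' @param p A `peptide`.
#' @return A single string.
#' @export
format_peptide <- function(p) {
  stopifnot(inherits(p, "peptide"))
  out <- p$sequence
  if (p$n_terminal_acetyl) out <- paste0("Ac-", out)
  if (length(p$modifications) > 0) {
    pos <- sort(as.integer(names(p$modifications)))
    for (i in pos) out <- paste0(out, "+", p$modifications[[as.character(i)]], "@", i)
  }
  out
}

#' Parse the serialized peptide format
#'
#' Inverse of [format_peptide()].
#'
#' @param text Serialized peptide, e.g. `"Ac-LAGKNLTHI+pyrrole@4"`.
#' @return A `peptide`.
#' @export
parse_peptide_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  acetyl <- startsWith(text, "Ac-")
  if (acetyl) text <- substring(text, 4)
  parts <- strsplit(text, "+", fixed = TRUE)[[1]]
  p <- parse_peptide(parts[1], acetylated = acetyl)
  for (tag in parts[-1]) {
    kv <- strsplit(tag, "@", fixed = TRUE)[[1]]
    if (length(kv) != 2) as_error("malformed modification tag '%s' (expected species@pos)", tag)
    p <- apply_adduct(p, as.integer(kv[2]), kv[1])
  }
  p
}
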