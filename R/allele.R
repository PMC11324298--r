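# MHC class I allele representation: supported peptide lengths, anchor
# positions, per-position groove-exposure profile, and an optional PSSM
# handle used by the surrogate scorer.

#' Construct an MHC-I allele model
#'
#' The groove-exposure profile assigns each peptide position a value in
#' \[0, 1\]: 1 means the side chain is fully solvent-exposed (pointing at the
#' T cell receptor, free to carry a bulky adduct), 0 means fully buried in
#' the groove. Anchor positions are, by construction, nearly buried.
#'
#' @param name Allele identifier, e.g. `"H-2Db"` or `"HLA-B*07:02"`.
#' @param supported_lengths Integer vector of peptide lengths in \[8, 10\].
#' @param anchors Named list mapping length (as character) to 1-based anchor
#'   position vectors.
#' @param exposure Named list mapping length to a numeric exposure vector of
#'   exactly that length with entries in \[0, 1\].
#' @param pssm Optional [pssm] object used by binder prediction and the
#'   surrogate scorer.
#' @return An `allele_model`.
#' @export
allele_model <- function(name, supported_lengths, anchors, exposure, pssm = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  supported_lengths <- as.integer(supported_lengths)
  if (any(supported_lengths < 8 | supported_lengths > 10)) {
    as_error("supported peptide lengths must lie in [8, 10]")
  }
  for (L in supported_lengths) {
    key <- as.character(L)
    a <- anchors[[key]]
    e <- exposure[[key]]
    if (is.null(a) || is.null(e)) as_error("anchors and exposure required for length %d", L)
    if (any(a < 1 | a > L)) as_error("anchor positions for length %d must lie in [1, %d]", L, L)
    if (length(e) != L) as_error("exposure vector for length %d must have %d entries", L, L)
    if (any(e < 0 | e > 1)) as_error("exposure values must lie in [0, 1]")
  }
  structure(list(name = name, supported_lengths = supported_lengths,
                 anchors = anchors, exposure = exposure, pssm = pssm),
            class = "allele_model")
}

#' @export
print.allele_model <- function(x, ...) {
  cat("<allele_model>", x$name, "- lengths:",
      paste(x$supported_lengths, collapse = ","), "\n")
  for (L in x$supported_lengths) {
    key <- as.character(L)
    cat(sprintf("  L=%d anchors {%s} exposure [%s]\n", L,
                paste(x$anchors[[key]], collapse = ","),
                paste(sprintf("%.2f", x$exposure[[key]]), collapse = " ")))
  }
  invisible(x)
}

#' Default mouse MHC-I allele models
#'
#' H-2Db presents 9-mers with anchors at P5 and P9; H-2Kb presents 8-mers
#' with anchors at P5 and P8 (the two C57BL/6 class I variants). Anchor
#' exposure defaults to 0.1 and non-anchor exposure to 0.6; these defaults
#' are configuration to be overridden with structure-derived profiles, not a
#' structural claim.
#'
#' @return Named list of two `allele_model` objects (`"H-2Db"`, `"H-2Kb"`).
#' @export
default_alleles <- function() {
  db_exp <- rep(0.6, 9); db_exp[c(5, 9)] <- 0.1
  kb_exp <- rep(0.6, 8); kb_exp[c(5, 8)] <- 0.1
  list(
    "H-2Db" = allele_model("H-2Db", 9L, list("9" = c(5L, 9L)), list("9" = db_exp)),
    "H-2Kb" = allele_model("H-2Kb", 8L, list("8" = c(5L, 8L)), list("8" = kb_exp))
  )
}

#' Attach a PSSM to an allele model
#'
#' @param allele An `allele_model`.
#' @param pssm A [pssm] object; its length must be among the allele's
#'   supported lengths.
#' @return The updated allele model.
#' @export
set_allele_pssm <- function(allele, pssm) {
  stopifnot(inherits(allele, "allele_model"), inherits(pssm, "pssm"))
  if (!(pssm$length %in% allele$supported_lengths)) {
    as_error("PSSM length %d not among allele's supported lengths", pssm$length)
  }
  allele$pssm <- pssm
  allele
}

#' Read allele definitions from TSV
#'
#' Columns: `name`, `length`, `anchors` (comma list), `exposure` (comma list
#' of reals). One row per (allele, length).
#'
#' @param path File path.
#' @return Named list of `allele_model` objects.
#' @export
read_allele_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "length", "anchors", "exposure")
  if (!all(need %in% names(df))) {
    as_error("allele table must have columns: %s", paste(need, collapse = ", "))
  }
  out <- list()
  for (nm in unique(df$name)) {
    rows <- df[df$name == nm, , drop = FALSE]
    anchors <- list(); exposure <- list()
    for (i in seq_len(nrow(rows))) {
      key <- as.character(rows$length[i])
      anchors[[key]] <- parse_int_csv(rows$anchors[i])
      exposure[[key]] <- as.numeric(strsplit(rows$exposure[i], ",", fixed = TRUE)[[1]])
    }
    out[[nm]] <- allele_model(nm, rows$length, anchors, exposure)
  }
  out
}

#' Write allele definitions to TSV
#'
#' @param alleles Named list of `allele_model` objects.
#' @param path Output path.
#' @export
write_allele_tsv <- function(alleles, path) {
  rows <- list()
  for (a in alleles) {
    for (L in a$supported_lengths) {
      key <- as.character(L)
      rows[[length(rows) + 1]] <- data.frame(
        name = a$name, length = L,
        anchors = paste(a$anchors[[key]], collapse = ","),
        exposure = paste(fmt_num(a$exposure[[key]], 4), collapse = ","))
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
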