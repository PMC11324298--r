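# Peptide-MHC structure templates: a minimal PDB dialect reader, template
# library construction, BLOSUM62 template selection, and threading of a
# query sequence onto a template backbone.

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Construct a template entry programmatically
#'
#' @param template_id Unique template identifier.
#' @param peptide_sequence Peptide sequence bound in the template groove.
#' @param backbone Numeric matrix, one row of (x, y, z) in Angstrom per
#'   peptide residue (C-alpha trace).
#' @param receptor_atoms Numeric matrix with columns (x, y, z, radius) of
#'   receptor pseudo-atom centers; may have zero rows.
#' @return A `template_entry`.
#' @export
template_entry <- function(template_id, peptide_sequence, backbone,
                           receptor_atoms = matrix(numeric(0), ncol = 4)) {
  backbone <- as.matrix(backbone)
  if (nrow(backbone) != nchar(peptide_sequence)) {
    as_error("template '%s': backbone has %d residues but peptide has %d",
             template_id, nrow(backbone), nchar(peptide_sequence))
  }
  parse_peptide(peptide_sequence)  # validates the alphabet
  structure(list(template_id = template_id,
                 peptide_sequence = peptide_sequence,
                 backbone = unname(backbone[, 1:3, drop = FALSE]),
                 receptor_atoms = unname(as.matrix(receptor_atoms))),
            class = "template_entry")
}

# Parse one PDB file under the minimal dialect: ATOM records only; altloc or
# insertion-code records invalidate the entry (per file, not fatally);
# peptide chain selected by `peptide_chain`; backbone = C-alpha trace;
# receptor pseudo-atoms = C-alpha atoms of all other chains at a constant
# radius.
parse_pdb_minimal <- function(path, peptide_chain = "C", receptor_radius = 1.8) {
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (length(atoms) == 0) return(list(ok = FALSE, reason = "no ATOM records"))
  fld <- function(x, a, b) substr(x, a, b)
  altloc <- trimws(fld(atoms, 17, 17))
  icode <- trimws(fld(atoms, 27, 27))
  if (any(nzchar(altloc)) || any(nzchar(icode))) {
    return(list(ok = FALSE, reason = "altloc/insertion-code records not supported"))
  }
  rec <- data.frame(
    name = trimws(fld(atoms, 13, 16)),
    resname = trimws(fld(atoms, 18, 20)),
    chain = fld(atoms, 22, 22),
    resseq = suppressWarnings(as.integer(fld(atoms, 23, 26))),
    x = suppressWarnings(as.numeric(fld(atoms, 31, 38))),
    y = suppressWarnings(as.numeric(fld(atoms, 39, 46))),
    z = suppressWarnings(as.numeric(fld(atoms, 47, 54))),
    stringsAsFactors = FALSE)
  if (anyNA(rec)) return(list(ok = FALSE, reason = "unparseable ATOM record"))
  pep <- rec[rec$chain == peptide_chain, , drop = FALSE]
  if (nrow(pep) == 0) {
    return(list(ok = FALSE, reason = sprintf("no peptide chain '%s'", peptide_chain)))
  }
  resseq <- sort(unique(pep$resseq))
  bb <- matrix(NA_real_, nrow = length(resseq), ncol = 3)
  seq1 <- character(length(resseq))
  for (i in seq_along(resseq)) {
    res <- pep[pep$resseq == resseq[i], , drop = FALSE]
    ca <- res[res$name == "CA", , drop = FALSE]
    if (nrow(ca) != 1) {
      return(list(ok = FALSE,
                  reason = sprintf("peptide residue %d lacks a unique CA record", resseq[i])))
    }
    one <- AA_THREE_TO_ONE[ca$resname]
    if (is.na(one)) {
      return(list(ok = FALSE,
                  reason = sprintf("non-canonical residue '%s' in peptide chain", ca$resname)))
    }
    seq1[i] <- one
    bb[i, ] <- c(ca$x, ca$y, ca$z)
  }
  rc <- rec[rec$chain != peptide_chain & rec$name == "CA", , drop = FALSE]
  receptor <- if (nrow(rc) > 0) {
    cbind(rc$x, rc$y, rc$z, receptor_radius)
  } else {
    matrix(numeric(0), ncol = 4)
  }
  list(ok = TRUE, peptide_sequence = paste(seq1, collapse = ""),
       backbone = bb, receptor_atoms = receptor)
}

#' Load a peptide-MHC template library from PDB files
#'
#' Reads each file under the minimal PDB dialect (ATOM records only;
#' configurable peptide chain id; coordinates in Angstrom; records carrying
#' altloc or insertion codes invalidate that entry, not the whole load).
#' Entries failing validation are skipped with a logged reason; template ids
#' default to the file base name and must be unique.
#'
#' @param paths Character vector of PDB file paths.
#' @param peptide_chain Chain id holding the peptide (default `"C"`).
#' @param ids Optional template ids (default: file base names).
#' @return A `template_library` (list of [template_entry()] objects).
#' @export
load_template_library <- function(paths, peptide_chain = "C", ids = NULL) {
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  if (anyDuplicated(ids)) {
    as_error("duplicate template_id '%s' across files", ids[duplicated(ids)][1])
  }
  entries <- list()
  for (i in seq_along(paths)) {
    parsed <- parse_pdb_minimal(paths[i], peptide_chain)
    if (!parsed$ok) {
      message(sprintf("skipping template '%s': %s", ids[i], parsed$reason))
      next
    }
    entries[[length(entries) + 1]] <- template_entry(
      ids[i], parsed$peptide_sequence, parsed$backbone, parsed$receptor_atoms)
  }
  template_library(entries)
}

#' Assemble a template library from entries
#'
#' @param entries List of [template_entry()] objects with unique ids.
#' @return A `template_library`.
#' @export
template_library <- function(entries) {
  if (length(entries) == 0) as_error("template library has zero valid entries")
  ids <- vapply(entries, function(e) e$template_id, character(1))
  if (anyDuplicated(ids)) {
    as_error("duplicate template_id '%s' in library", ids[duplicated(ids)][1])
  }
  structure(stats::setNames(entries, ids), class = "template_library")
}

#' Ungapped substitution-matrix alignment score
#'
#' Position-wise sum of substitution scores between two equal-length
#' sequences (no gaps: same-length peptides are modeled end-to-end in the
#' MHC groove).
#'
#' @param a,b Equal-length sequence strings.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @return Numeric score.
#' @export
alignment_score <- function(a, b, matrix = blosum62()) {
  if (nchar(a) != nchar(b)) as_error("alignment_score requires equal-length sequences")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(matrix[cbind(ca, cb)])
}

#' Select the best template for a query peptide
#'
#' Among same-length library entries, returns the one maximizing the
#' ungapped BLOSUM62 score against the query; length-mismatched templates
#' are excluded; ties broken by lexicographically smallest template id.
#'
#' @param query Query peptide sequence string.
#' @param lib A `template_library`.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @return List with `template` (the winning [template_entry()]) and `score`.
#' @export
select_template <- function(query, lib, matrix = blosum62()) {
  stopifnot(inherits(lib, "template_library"))
  same_len <- Filter(function(e) nchar(e$peptide_sequence) == nchar(query), lib)
  if (length(same_len) == 0) {
    as_error("no template of length %d in library", nchar(query))
  }
  scores <- vapply(same_len, function(e) alignment_score(query, e$peptide_sequence, matrix),
                   numeric(1))
  ids <- vapply(same_len, function(e) e$template_id, character(1))
  best <- max(scores)
  winner_id <- sort(ids[scores == best], method = "radix")[1]
  list(template = same_len[[which(ids == winner_id)]], score = best)
}

#' Thread a query peptide onto a template backbone
#'
#' Builds a complex model whose peptide is the query and whose backbone and
#' receptor pseudo-atoms are copied unchanged from the template (residue
#' identities swapped in place; coordinates untouched). Deterministic.
#'
#' @param template A [template_entry()].
#' @param query A `peptide` or sequence string of the same length as the
#'   template peptide.
#' @return A `complex_model`.
#' @export
thread_peptide <- function(template, query) {
  stopifnot(inherits(template, "template_entry"))
  if (is.character(query)) query <- parse_peptide(query)
  if (nchar(query$sequence) != nchar(template$peptide_sequence)) {
    as_error("query length %d does not match template peptide length %d",
             nchar(query$sequence), nchar(template$peptide_sequence))
  }
  complex_model(query, backbone = template$backbone,
                receptor_atoms = template$receptor_atoms,
                template_id = template$template_id)
}

#' Construct a peptide-MHC complex model
#'
#' A threaded complex: the query peptide plus backbone / receptor geometry
#' inherited from its template. `backbone = NULL` builds a geometry-free
#' complex, sufficient for the surrogate scorer when the clash term is
#' disabled.
#'
#' @param peptide A `peptide` or sequence string.
#' @param backbone Optional C-alpha coordinate matrix (one row per residue).
#' @param receptor_atoms Optional receptor pseudo-atom matrix (x, y, z, radius).
#' @param template_id Provenance string.
#' @return A `complex_model`.
#' @export
complex_model <- function(peptide, backbone = NULL,
                          receptor_atoms = matrix(numeric(0), ncol = 4),
                          template_id = NA_character_) {
  if (is.character(peptide)) peptide <- parse_peptide(peptide)
  stopifnot(inherits(peptide, "peptide"))
  if (!is.null(backbone)) {
    backbone <- as.matrix(backbone)
    if (nrow(backbone) != nchar(peptide$sequence)) {
      as_error("backbone rows (%d) must equal peptide length (%d)",
               nrow(backbone), nchar(peptide$sequence))
    }
  }
  structure(list(peptide = peptide, backbone = backbone,
                 receptor_atoms = as.matrix(receptor_atoms),
                 template_id = template_id),
            class = "complex_model")
}
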