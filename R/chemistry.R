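# Monoisotopic mass arithmetic: element table, residue compositions,
# adduct species registry, peptide mass and PRM precursor m/z.

# Residue (not free amino acid) elemental compositions, columns C H N O S.
AA_COMPOSITION <- matrix(c(
  # C  H  N  O  S
    3,  5, 1, 1, 0,  # A
    6, 12, 4, 1, 0,  # R
    4,  6, 2, 2, 0,  # N
    4,  5, 1, 3, 0,  # D
    3,  5, 1, 1, 1,  # C
    5,  8, 2, 2, 0,  # Q
    5,  7, 1, 3, 0,  # E
    2,  3, 1, 1, 0,  # G
    6,  7, 3, 1, 0,  # H
    6, 11, 1, 1, 0,  # I
    6, 11, 1, 1, 0,  # L
    6, 12, 2, 1, 0,  # K
    5,  9, 1, 1, 1,  # M
    9,  9, 1, 1, 0,  # F
    5,  7, 1, 1, 0,  # P
    3,  5, 1, 2, 0,  # S
    4,  7, 1, 2, 0,  # T
   11, 10, 2, 1, 0,  # W
    9,  9, 1, 2, 0,  # Y
    5,  9, 1, 1, 0   # V
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET, c("C", "H", "N", "O", "S")))

#' Monoisotopic element mass table
#'
#' Loads the shipped element table (element symbol to monoisotopic mass in
#' Da, plus the proton mass), or a user-supplied override in the same
#' two-column TSV layout with a `proton` row.
#'
#' @param path Optional path to an alternative table.
#' @return An `element_table`: list with `masses` (named numeric, Da) and
#'   `proton` (Da).
#' @export
element_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "elements.tsv", package = "adductscan",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  masses <- stats::setNames(df$monoisotopic_mass, df$element)
  if (any(masses <= 0)) as_error("element masses must be strictly positive")
  proton <- masses[["proton"]]
  masses <- masses[names(masses) != "proton"]
  structure(list(masses = masses, proton = proton), class = "element_table")
}

#' Define an adduct species
#'
#' A lysine-adduct chemotype: a signed elemental-composition delta applied to
#' the peptide on adduction, and a nonnegative unitless bulk weight used by
#' the surrogate accommodation penalty.
#'
#' @param name Species name, e.g. `"pyrrole"`.
#' @param delta Named integer vector, element symbol to signed atom count.
#' @param bulk_weight Nonnegative accommodation-penalty weight.
#' @return An `adduct_species`.
#' @export
adduct_species <- function(name, delta, bulk_weight = 1) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  delta <- stats::setNames(as.numeric(delta), names(delta))
  if (is.null(names(delta)) || any(!nzchar(names(delta)))) {
    as_error("elemental delta must be a named element -> count map")
  }
  if (bulk_weight < 0) as_error("bulk_weight must be >= 0")
  structure(list(name = name, delta = delta, bulk_weight = as.numeric(bulk_weight)),
            class = "adduct_species")
}

#' Build an adduct registry
#'
#' @param species List of [adduct_species()] objects; names must be unique.
#' @return An `adduct_registry` (named list of species).
#' @export
adduct_registry <- function(species) {
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    as_error("duplicate adduct species name '%s' in registry", nm[duplicated(nm)][1])
  }
  structure(stats::setNames(species, nm), class = "adduct_registry")
}

#' The default IsoLG lysine-adduct registry
#'
#' Ships the four adduct chemotypes observed for isolevuglandin on lysine
#' epsilon-amines: pyrrole, lactam, anhydrolactam and anhydropyrrole. The
#' elemental deltas are documented placeholders derived from the IsoLG
#' (C20H32O4) + lysine condensation series (pyrrole = IsoLG - 2 H2O; lactam =
#' pyrrole + O; each anhydro form = parent - H2O); override them with a
#' chemistry config ([read_chemistry_config()]) when instrument-calibrated
#' compositions are available.
#'
#' @param path Optional chemistry config path; defaults to the shipped file.
#' @return An `adduct_registry`.
#' @export
default_adduct_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "isolg_adducts.yaml", package = "adductscan",
                        mustWork = TRUE)
  }
  read_chemistry_config(path)
}

#' Read a chemistry config file
#'
#' YAML mapping species name to an elemental delta and bulk weight:
#' ```yaml
#' species:
#'   pyrrole: {delta: {C: 20, H: 28, O: 2}, bulk_weight: 1.0}
#' ```
#'
#' @param path Config file path.
#' @return An `adduct_registry`.
#' @export
read_chemistry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species)) as_error("chemistry config must have a 'species' block")
  sp <- lapply(names(cfg$species), function(nm) {
    entry <- cfg$species[[nm]]
    adduct_species(nm, unlist(entry$delta), entry$bulk_weight %||% 1)
  })
  adduct_registry(sp)
}

# Mass of a signed elemental composition under an element table.
formula_mass <- function(delta, table) {
  unknown <- setdiff(names(delta), names(table$masses))
  if (length(unknown) > 0) as_error("unknown element '%s' in formula", unknown[1])
  sum(delta * table$masses[names(delta)])
}

#' Monoisotopic mass of a (possibly modified) peptide
#'
#' Sum of residue masses plus one water, plus an acetyl group (C2H2O) if the
#' peptide is N-terminally acetylated, plus the elemental delta of every
#' recorded adduct. Additivity holds exactly: modifying a peptide changes its
#' mass by precisely the species' delta mass.
#'
#' @param p A `peptide`.
#' @param table An [element_table()].
#' @param registry An `adduct_registry` resolving modification names.
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(p, table = element_table(),
                              registry = default_adduct_registry()) {
  stopifnot(inherits(p, "peptide"))
  chars <- strsplit(p$sequence, "")[[1]]
  comp <- colSums(AA_COMPOSITION[chars, , drop = FALSE])
  comp["H"] <- comp["H"] + 2
  comp["O"] <- comp["O"] + 1                      # + H2O
  if (p$n_terminal_acetyl) {
    comp["C"] <- comp["C"] + 2
    comp["H"] <- comp["H"] + 2
    comp["O"] <- comp["O"] + 1                    # + C2H2O
  }
  mass <- formula_mass(comp, table)
  for (nm in unlist(p$modifications, use.names = FALSE)) {
    if (is.null(registry[[nm]])) {
      as_error("adduct species '%s' not in registry (have: %s)", nm,
               paste(names(registry), collapse = ", "))
    }
    mass <- mass + formula_mass(registry[[nm]]$delta, table)
  }
  mass
}

#' Precursor m/z of a peptide at a given charge
#'
#' `(M + z * m_proton) / z` for the monoisotopic mass `M`.
#'
#' @inheritParams monoisotopic_mass
#' @param z Positive integer charge.
#' @return m/z in Th.
#' @export
precursor_mz <- function(p, z, table = element_table(),
                         registry = default_adduct_registry()) {
  z <- as.integer(z)
  if (any(z < 1)) as_error("charge z must be >= 1")
  m <- monoisotopic_mass(p, table, registry)
  (m + z * table$proton) / z
}

#' PRM precursor target table for an adducted peptide
#'
#' For parallel-reaction-monitoring target lists: computes precursor m/z for
#' the peptide carrying each requested adduct species at a lysine position,
#' over the requested charge states (the assay monitors singly and doubly
#' charged species of the N-acetylated adducted peptides by default).
#'
#' @param sequence Peptide sequence string.
#' @param position 1-based lysine position to adduct.
#' @param species Character vector of species names; default all registered.
#' @param charges Integer charges; default `c(1, 2)`.
#' @param acetylated Logical N-terminal acetylation flag; default `TRUE`.
#' @inheritParams monoisotopic_mass
#' @return Data frame with columns `species`, `z`, `mz`.
#' @export
prm_targets <- function(sequence, position, species = NULL, charges = c(1, 2),
                        acetylated = TRUE, table = element_table(),
                        registry = default_adduct_registry()) {
  if (is.null(species)) species <- names(registry)
  base <- parse_peptide(sequence, acetylated = acetylated)
  rows <- lapply(species, function(sp) {
    mod <- apply_adduct(base, position, sp)
    data.frame(species = sp, z = as.integer(charges),
               mz = vapply(charges, function(z) precursor_mz(mod, z, table, registry),
                           numeric(1)))
  })
  do.call(rbind, rows)
}
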