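# Scoring backends and the delta-score statistic. The default surrogate
# replaces the all-atom energy with a transparent model: a PSSM binding term
# plus an exposure-driven adduct accommodation penalty (optional clash
# count). Lower scores are more favorable.

.backends <- new.env(parent = emptyenv())

#' Surrogate scorer parameters
#'
#' @param penalty_scale Nonnegative scale (kappa) of the accommodation
#'   penalty, in surrogate score units per unit bulk weight (default 10).
#' @param clash_radius Clash-count radius in Angstrom (default 2.5).
#' @param clash_weight Nonnegative weight per counted clash (default 1).
#' @param clash_term_enabled Enable the clash-count term (default `FALSE`,
#'   keeping worked examples closed-form).
#' @return A `surrogate_params` list.
#' @export
surrogate_params <- function(penalty_scale = 10, clash_radius = 2.5,
                             clash_weight = 1, clash_term_enabled = FALSE) {
  if (penalty_scale < 0) as_error("penalty_scale must be >= 0")
  if (clash_radius <= 0) as_error("clash_radius must be > 0")
  if (clash_weight < 0) as_error("clash_weight must be >= 0")
  structure(list(penalty_scale = penalty_scale, clash_radius = clash_radius,
                 clash_weight = clash_weight,
                 clash_term_enabled = isTRUE(clash_term_enabled)),
            class = "surrogate_params")
}

#' Register a scoring backend
#'
#' A backend is a callable `function(model, allele, params)` returning a
#' list with `total` and `per_position` (summing to `total`). The surrogate
#' backend is pre-registered; an adapter slot for external all-atom scorers
#' registers the same way.
#'
#' @param name Unused backend name.
#' @param fn Scoring callable.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  if (!is.null(.backends[[name]])) {
    as_error("backend '%s' is already registered", name)
  }
  assign(name, fn, envir = .backends)
  invisible(NULL)
}

#' List registered backend names
#' @return Character vector.
#' @export
list_backends <- function() sort(ls(.backends))

# Drop every backend except the built-in surrogate (test hygiene).
reset_backends <- function() {
  rm(list = setdiff(ls(.backends), "surrogate"), envir = .backends)
  invisible(NULL)
}

clash_count <- function(model, i, params) {
  if (is.null(model$backbone) || nrow(model$receptor_atoms) == 0) return(0)
  d2 <- colSums((t(model$receptor_atoms[, 1:3, drop = FALSE]) - model$backbone[i, ])^2)
  sum(d2 < params$clash_radius^2)
}

#' Adduct accommodation penalty at a position
#'
#' `penalty = kappa * bulk_weight * (1 - exposure[i])`, plus, when enabled,
#' `clash_weight` times the number of receptor pseudo-atoms within
#' `clash_radius` of the position's backbone coordinate. A fully exposed
#' position (exposure 1) accommodates the adduct at zero cost; a fully
#' buried one pays the full bulk penalty.
#'
#' @param i 1-based peptide position.
#' @param species An `adduct_species` or registered species name.
#' @param allele An `allele_model` with an exposure profile for the length.
#' @param params [surrogate_params()].
#' @param length Peptide length selecting the exposure profile (default: the
#'   allele's single supported length).
#' @param model Optional `complex_model` (needed only for the clash term).
#' @param registry Adduct registry used to resolve species names.
#' @return Nonnegative penalty.
#' @export
adduct_penalty <- function(i, species, allele, params = surrogate_params(),
                           length = NULL, model = NULL,
                           registry = default_adduct_registry()) {
  if (is.character(species)) {
    if (is.null(registry[[species]])) as_error("unknown adduct species '%s'", species)
    species <- registry[[species]]
  }
  L <- length %||% allele$supported_lengths[1]
  exposure <- allele$exposure[[as.character(L)]]
  if (i < 1 || i > L) as_error("position %d outside [1, %d]", i, L)
  pen <- params$penalty_scale * species$bulk_weight * (1 - exposure[i])
  if (params$clash_term_enabled) {
    if (is.null(model) || is.null(model$backbone)) {
      as_error("clash term enabled but no backbone geometry available")
    }
    pen <- pen + params$clash_weight * clash_count(model, i, params)
  }
  pen
}

# The built-in surrogate backend.
surrogate_backend <- function(model, allele, params,
                              registry = default_adduct_registry()) {
  p <- model$peptide
  L <- nchar(p$sequence)
  pssm <- allele$pssm
  if (is.null(pssm)) as_error("allele '%s' has no PSSM attached", allele$name)
  if (pssm$length != L) {
    as_error("allele PSSM length %d does not match peptide length %d", pssm$length, L)
  }
  chars <- strsplit(p$sequence, "")[[1]]
  per_pos <- -pssm$matrix[cbind(seq_len(L), match(chars, AA_ALPHABET))]
  for (key in names(p$modifications)) {
    i <- as.integer(key)
    per_pos[i] <- per_pos[i] +
      adduct_penalty(i, p$modifications[[key]], allele, params,
                     length = L, model = model, registry = registry)
  }
  list(total = sum(per_pos), per_position = per_pos)
}

#' Score a peptide-MHC complex
#'
#' Dispatches to a registered backend (default: the surrogate). Under the
#' surrogate, each position contributes the negated PSSM log-odds entry for
#' its residue, plus the accommodation penalty when the position carries an
#' adduct; unmodified positions contribute no penalty. Lower total = more
#' favorable. Scoring is a pure function: repeated calls are bit-identical.
#'
#' `n_models` and `top_k` are accepted for interface parity with external
#' ensemble backends (which generate many models and average the best k);
#' the deterministic surrogate ignores them by contract.
#'
#' @param model A `complex_model`.
#' @param allele An `allele_model` whose supported lengths include the
#'   peptide's length and whose PSSM is attached.
#' @param params [surrogate_params()].
#' @param backend Registered backend name (default `"surrogate"`).
#' @param registry Adduct registry.
#' @param n_models,top_k Ensemble-interface no-ops for the surrogate.
#' @return A `score_report`: `total`, `per_position`, `backend`, `adducted`,
#'   `adduct_position`, `species`.
#' @export
score_complex <- function(model, allele, params = surrogate_params(),
                          backend = "surrogate",
                          registry = default_adduct_registry(),
                          n_models = 1, top_k = 1) {
  stopifnot(inherits(model, "complex_model"), inherits(allele, "allele_model"))
  L <- nchar(model$peptide$sequence)
  if (!(L %in% allele$supported_lengths)) {
    as_error("peptide length %d not supported by allele '%s' (lengths: %s)",
             L, allele$name, paste(allele$supported_lengths, collapse = ","))
  }
  fn <- .backends[[backend]]
  if (is.null(fn)) {
    as_error("unknown backend '%s'; registered backends: {%s}",
             backend, paste(list_backends(), collapse = ", "))
  }
  res <- if (identical(backend, "surrogate")) {
    fn(model, allele, params, registry = registry)
  } else {
    fn(model, allele, params)
  }
  mods <- model$peptide$modifications
  pos <- if (length(mods) > 0) sort(as.integer(names(mods))) else integer(0)
  structure(list(
    total = res$total,
    per_position = res$per_position,
    backend = backend,
    adducted = length(mods) > 0,
    adduct_position = pos,
    species = if (length(pos) > 0) {
      unlist(mods[as.character(pos)], use.names = FALSE)
    } else {
      character(0)
    }), class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> backend=%s total=%.4f adducted=%s\n",
              x$backend, x$total, x$adducted))
  invisible(x)
}

#' Score a peptide against an allele without template geometry
#'
#' Convenience wrapper building a geometry-free complex; valid for the
#' surrogate whenever the clash term is disabled.
#'
#' @param peptide A `peptide` or sequence string.
#' @param allele An `allele_model` with a PSSM.
#' @inheritParams score_complex
#' @return A `score_report`.
#' @export
score_peptide_allele <- function(peptide, allele, params = surrogate_params(),
                                 backend = "surrogate",
                                 registry = default_adduct_registry()) {
  score_complex(complex_model(peptide), allele, params, backend, registry)
}

#' Delta score of in-silico adduction
#'
#' `delta = score(adducted at i).total - score(unadducted).total`. Small or
#' zero values mean the groove accommodates the adduct at that position;
#' under the surrogate (clash term off) the delta equals
#' [adduct_penalty()] exactly.
#'
#' @param model A `complex_model` whose peptide is unmodified at `i`.
#' @param i 1-based lysine position to adduct.
#' @param species `adduct_species` or registered name.
#' @inheritParams score_complex
#' @return Numeric delta score (nonnegative under the surrogate).
#' @export
delta_score <- function(model, i, species, allele, params = surrogate_params(),
                        backend = "surrogate",
                        registry = default_adduct_registry()) {
  stopifnot(inherits(model, "complex_model"))
  res <- substr(model$peptide$sequence, i, i)
  if (res != "K") {
    as_error("position %d is '%s', not a lysine; delta_score targets K", i, res)
  }
  name <- if (inherits(species, "adduct_species")) species$name else species
  before <- score_complex(model, allele, params, backend, registry)
  mod <- model
  mod$peptide <- apply_adduct(model$peptide, i, name)
  after <- score_complex(mod, allele, params, backend, registry)
  after$total - before$total
}

#' Write a score report as TSV
#'
#' One row per position plus a `total` row.
#'
#' @param report A `score_report`.
#' @param peptide The scored `peptide` (for residue annotation).
#' @param path Output path.
#' @export
write_score_report_tsv <- function(report, peptide, path) {
  chars <- strsplit(peptide$sequence, "")[[1]]
  df <- data.frame(position = c(seq_along(chars), NA),
                   residue = c(chars, "total"),
                   score = c(report$per_position, report$total))
  write_tsv_plain(df, path)
}
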