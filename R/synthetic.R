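# Seeded synthetic-data generators with planted ground truth. Every input
# the pipeline consumes (allele profiles, PSSMs, epitope sets, proteome +
# expression + ortholog fixtures) can be generated offline; all generators
# are pure functions of (spec, seed) via named sub-seeded RNG streams.

#' Specification of a planted synthetic instance
#'
#' @param seed Master integer seed; every generator derives a named
#'   sub-stream from it.
#' @param length Peptide length (default 9).
#' @param favorable Favorable adduction positions planted at exposure 1.0
#'   (default `c(4, 6, 7)`).
#' @param anchors Anchor positions (default `c(5, 9)`); must be disjoint
#'   from `favorable`.
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param n_planted Number of planted candidate peptides (each embedded in
#'   one high-fold protein); at most `length(favorable)` unless explicit
#'   `planted_candidates` are supplied.
#' @param planted_candidates Optional list of `list(sequence, k_pos)`
#'   entries; planted lysine positions must lie in `favorable`.
#' @param fold_high Kidney fold change of planted proteins (default 8).
#' @param fold_background_max Upper bound of background protein folds
#'   (default 3, below the screening threshold).
#' @param pssm_sharpness Softmax concentration of the planted PSSM (default
#'   6: consensus frequency about 0.95, an anchor-like sharp motif).
#' @param n_binders,n_nonbinders Epitope set sizes (default 200 each).
#' @param affinity_sigma Noise s.d. of log10 IC50 (default 0.5).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(seed = 1, length = 9, favorable = c(4, 6, 7),
                       anchors = c(5, 9), n_proteins = 12, n_planted = 2,
                       planted_candidates = NULL, fold_high = 8,
                       fold_background_max = 3, pssm_sharpness = 6,
                       n_binders = 200, n_nonbinders = 200,
                       affinity_sigma = 0.5) {
  favorable <- sort(as.integer(favorable))
  anchors <- sort(as.integer(anchors))
  if (length(intersect(favorable, anchors)) > 0) {
    as_error("favorable positions {%s} overlap anchors {%s}",
             paste(favorable, collapse = ","), paste(anchors, collapse = ","))
  }
  if (any(c(favorable, anchors) < 1 | c(favorable, anchors) > length)) {
    as_error("favorable/anchor positions must lie in [1, %d]", length)
  }
  if (is.null(planted_candidates) && n_planted > base::length(favorable)) {
    as_error("n_planted > %d needs explicit planted_candidates", base::length(favorable))
  }
  if (!is.null(planted_candidates)) {
    for (pc in planted_candidates) {
      parse_peptide(pc$sequence)
      if (nchar(pc$sequence) != length) as_error("planted sequences must have length %d", length)
      if (!(pc$k_pos %in% favorable)) {
        as_error("planted lysine position %d not in favorable set", pc$k_pos)
      }
      if (substr(pc$sequence, pc$k_pos, pc$k_pos) != "K") {
        as_error("planted sequence lacks K at its stated position %d", pc$k_pos)
      }
    }
    n_planted <- base::length(planted_candidates)
  }
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 favorable = favorable, anchors = anchors,
                 n_proteins = as.integer(n_proteins),
                 n_planted = as.integer(n_planted),
                 planted_candidates = planted_candidates,
                 fold_high = fold_high,
                 fold_background_max = fold_background_max,
                 pssm_sharpness = pssm_sharpness,
                 n_binders = as.integer(n_binders),
                 n_nonbinders = as.integer(n_nonbinders),
                 affinity_sigma = affinity_sigma),
            class = "plant_spec")
}

#' Generate a synthetic allele model
#'
#' Exposure 1.0 at the planted favorable positions, 0.1 at anchors, and a
#' seeded draw in \[0.15, 0.4\] elsewhere (solvent-accessible sites fully
#' exposed; everything else partially buried). Deterministic per seed.
#'
#' @param spec A [plant_spec()].
#' @param pssm Optional PSSM to attach.
#' @param name Allele name (default `"SYN-Db"`).
#' @return An `allele_model`.
#' @export
gen_allele <- function(spec, pssm = NULL, name = "SYN-Db") {
  stopifnot(inherits(spec, "plant_spec"))
  L <- spec$length
  exposure <- with_stream_seed(spec$seed, "allele", stats::runif(L, 0.15, 0.4))
  exposure[spec$favorable] <- 1.0
  exposure[spec$anchors] <- 0.1
  key <- as.character(L)
  a <- allele_model(name, L, stats::setNames(list(spec$anchors), key),
                    stats::setNames(list(exposure), key))
  if (!is.null(pssm)) a <- set_allele_pssm(a, pssm)
  a
}

#' Generate a planted PSSM
#'
#' Draws a lysine-free consensus sequence, then sets each position's residue
#' frequencies by a softmax concentrated on the consensus:
#' `f(consensus) = exp(s) / (exp(s) + 19)` at sharpness `s`.
#'
#' @param spec A [plant_spec()].
#' @return A [pssm][new_pssm()] with the consensus stored in attribute
#'   `"consensus"`.
#' @export
gen_pssm <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  non_k <- setdiff(AA_ALPHABET, "K")
  consensus <- with_stream_seed(spec$seed, "pssm",
                                sample(non_k, spec$length, replace = TRUE))
  s <- spec$pssm_sharpness
  freqs <- matrix(1 / (exp(s) + 19), nrow = spec$length, ncol = 20,
                  dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(spec$length)) freqs[i, consensus[i]] <- exp(s) / (exp(s) + 19)
  p <- new_pssm(freqs)
  attr(p, "consensus") <- paste(consensus, collapse = "")
  p
}

#' Sample sequences from a PSSM's column distributions
#'
#' @param pssm A [pssm][new_pssm()].
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
sample_from_pssm <- function(pssm, n, seed = 1) {
  with_stream_seed(seed, "pssm-sample", {
    cols <- vapply(seq_len(pssm$length), function(i) {
      sample(AA_ALPHABET, n, replace = TRUE, prob = pssm$freqs[i, ])
    }, character(n))
    apply(matrix(cols, nrow = n), 1, paste, collapse = "")
  })
}

#' Generate peptides with one lysine cycling over non-anchor positions
#'
#' Used for per-position delta-score studies: peptide `j` carries a single
#' K at the `j`-th non-anchor position (cycling), all other residues drawn
#' lysine-free, so every non-anchor position receives `floor(n / n_pos)` or
#' more observations.
#'
#' @param spec A [plant_spec()].
#' @param n Number of peptides (default: two full cycles).
#' @return Data frame (`peptide_id`, `sequence`, `k_position`).
#' @export
gen_lysine_peptides <- function(spec, n = NULL) {
  stopifnot(inherits(spec, "plant_spec"))
  positions <- setdiff(seq_len(spec$length), spec$anchors)
  if (is.null(n)) n <- 2L * length(positions)
  non_k <- setdiff(AA_ALPHABET, "K")
  with_stream_seed(spec$seed, "peptides", {
    kpos <- positions[((seq_len(n) - 1) %% length(positions)) + 1]
    seqs <- vapply(seq_len(n), function(j) {
      chars <- sample(non_k, spec$length, replace = TRUE)
      chars[kpos[j]] <- "K"
      paste(chars, collapse = "")
    }, character(1))
    data.frame(peptide_id = sprintf("pep%03d", seq_len(n)), sequence = seqs,
               k_position = kpos, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic epitope dataset with planted affinity coupling
#'
#' Binder sequences are sampled from the PSSM's column distributions;
#' nonbinders are uniform-composition. Affinity is coupled to the PSSM
#' score: `log10(IC50) = a - b * score + Normal(0, sigma)`, with `a`, `b`
#' calibrated from the expected binder and nonbinder scores so planted
#' binders fall at 10^1.5 = 32 nM (well below the 500 nM threshold) and
#' nonbinders at 10^4.5 nM in expectation.
#'
#' @param spec A [plant_spec()].
#' @param pssm The planted [pssm][new_pssm()].
#' @param allele_name Allele label recorded on each row.
#' @return Data frame (`sequence`, `ic50_nm`, `allele`, `planted`) where
#'   `planted` is the generating class label.
#' @export
gen_epitope_dataset <- function(spec, pssm, allele_name = "SYN-Db") {
  stopifnot(inherits(spec, "plant_spec"), inherits(pssm, "pssm"))
  m <- pssm$matrix
  s_b <- sum(vapply(seq_len(pssm$length), function(i) sum(pssm$freqs[i, ] * m[i, ]),
                    numeric(1)))
  s_n <- sum(rowMeans(m))
  b <- 3 / (s_b - s_n)
  a <- 1.5 + b * s_b
  binders <- sample_from_pssm(pssm, spec$n_binders, seed = stream_seed(spec$seed, "epi-b"))
  nonbinders <- with_stream_seed(spec$seed, "epi-n", {
    idx <- matrix(sample(AA_ALPHABET, spec$n_nonbinders * spec$length, replace = TRUE),
                  nrow = spec$n_nonbinders)
    apply(idx, 1, paste, collapse = "")
  })
  seqs <- c(binders, nonbinders)
  scores <- score_peptide(seqs, pssm)
  noise <- with_stream_seed(spec$seed, "epi-noise",
                            stats::rnorm(length(seqs), 0, spec$affinity_sigma))
  ic50 <- 10^(a - b * scores + noise)
  data.frame(sequence = seqs, ic50_nm = ic50, allele = allele_name,
             planted = rep(c("binder", "nonbinder"),
                           c(spec$n_binders, spec$n_nonbinders)),
             stringsAsFactors = FALSE)
}

# Default planted candidates: the PSSM consensus with K substituted at
# successive favorable positions.
default_planted <- function(spec, pssm) {
  consensus <- attr(pssm, "consensus")
  lapply(seq_len(spec$n_planted), function(j) {
    k_pos <- spec$favorable[j]
    seq <- consensus
    substr(seq, k_pos, k_pos) <- "K"
    list(sequence = seq, k_pos = k_pos)
  })
}

#' Generate a synthetic proteome with planted screening truth
#'
#' Each planted candidate 9-mer is embedded once, between lysine-free
#' flanks, in a protein overexpressed in the kidney at `fold_high`;
#' background proteins sit below the fold threshold. A deterministic repair
#' pass guarantees that no window other than a planted frame can pass the
#' combined strong-binder + favorable-lysine filters: flanks carry no
#' lysine, and any frame in which the planted K lands on a favorable
#' position is driven below the expected background score by mutating flank
#' residues to the column-minimum residue. The returned truth list is
#' therefore exactly the set of fully passing candidates.
#'
#' @param spec A [plant_spec()].
#' @param pssm The planted [pssm][new_pssm()] (default [gen_pssm()]).
#' @return List with `proteome` (named character), `expression`,
#'   `orthologs`, `truth` (data frame `protein`, `start`, `peptide`,
#'   `lysine_positions`, `from`).
#' @export
gen_proteome <- function(spec, pssm = gen_pssm(spec)) {
  stopifnot(inherits(spec, "plant_spec"))
  planted <- spec$planted_candidates %||% default_planted(spec, pssm)
  if (anyDuplicated(vapply(planted, function(p) p$sequence, character(1)))) {
    as_error("planted candidate sequences must be distinct")
  }
  L <- spec$length
  flank <- 15L
  non_k <- setdiff(AA_ALPHABET, "K")
  m <- pssm$matrix
  mu_bg <- sum(rowMeans(m))
  n_bg <- spec$n_proteins - length(planted)
  if (n_bg < 1) as_error("n_proteins must exceed the number of planted candidates")

  with_stream_seed(spec$seed, "proteome", {
    mouse_ids <- sprintf("MMP%03d", seq_len(spec$n_proteins))
    human_ids <- sprintf("HSP%03d", seq_len(spec$n_proteins))
    seqs <- character(spec$n_proteins)

    for (j in seq_along(planted)) {
      chars <- c(sample(non_k, flank, replace = TRUE),
                 strsplit(planted[[j]]$sequence, "")[[1]],
                 sample(non_k, flank, replace = TRUE))
      planted_start <- flank + 1L
      # repair: no off-frame window may reach background-beating scores
      # while carrying the planted K at a favorable position
      for (pass in 1:20) {
        changed <- FALSE
        for (s in seq_len(length(chars) - L + 1)) {
          if (s == planted_start) next
          w <- chars[s:(s + L - 1)]
          kw <- which(w == "K")
          if (!any(kw %in% spec$favorable)) next
          sc <- sum(m[cbind(seq_len(L), match(w, AA_ALPHABET))])
          if (sc <= mu_bg) next
          in_plant <- (s + seq_len(L) - 1) >= planted_start &
                      (s + seq_len(L) - 1) <= planted_start + L - 1
          flank_pos <- which(!in_plant)
          j_mut <- flank_pos[which.max(m[cbind(flank_pos, match(w[flank_pos], AA_ALPHABET))])]
          col <- m[j_mut, ]
          col[match("K", AA_ALPHABET)] <- Inf  # never introduce a lysine
          chars[s + j_mut - 1] <- AA_ALPHABET[which.min(col)]
          changed <- TRUE
        }
        if (!changed) break
      }
      seqs[j] <- paste(chars, collapse = "")
    }
    for (j in seq(length(planted) + 1, spec$n_proteins)) {
      seqs[j] <- paste(sample(AA_ALPHABET, 60, replace = TRUE), collapse = "")
    }
    proteome <- stats::setNames(seqs, mouse_ids)

    tissues <- c("kidney", "liver", "lung", "heart", "brain", "spleen")
    expr_rows <- lapply(seq_len(spec$n_proteins), function(j) {
      others <- stats::runif(length(tissues) - 1, 5, 15)
      kidney <- if (j <= length(planted)) {
        max(others) * spec$fold_high
      } else {
        max(others) * stats::runif(1, 0.1, spec$fold_background_max)
      }
      data.frame(protein = human_ids[j], tissue = tissues,
                 expression = c(kidney, others), stringsAsFactors = FALSE)
    })
    expression <- do.call(rbind, expr_rows)

    # last background protein left unmapped to exercise dropped-id reporting
    keep <- seq_len(spec$n_proteins - 1)
    orthologs <- data.frame(from = human_ids[keep], to = mouse_ids[keep],
                            stringsAsFactors = FALSE)

    truth <- data.frame(
      protein = mouse_ids[seq_along(planted)],
      start = rep(flank + 1L, length(planted)),
      peptide = vapply(planted, function(p) p$sequence, character(1)),
      lysine_positions = vapply(planted, function(p) as.character(p$k_pos), character(1)),
      from = human_ids[seq_along(planted)],
      stringsAsFactors = FALSE)

    list(proteome = proteome, expression = expression,
         orthologs = orthologs, truth = truth)
  })
}

#' Write the full synthetic fixture set to disk
#'
#' FASTA proteome plus expression, ortholog, truth, allele, PSSM and epitope
#' files, all derived from one seed.
#'
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @param spec Optional [plant_spec()] overriding the default built from
#'   `seed`.
#' @return Invisibly, the named vector of written paths.
#' @export
make_fixtures <- function(seed, dir, spec = plant_spec(seed = seed)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pssm <- gen_pssm(spec)
  allele <- gen_allele(spec, pssm)
  prot <- gen_proteome(spec, pssm)
  epi <- gen_epitope_dataset(spec, pssm, allele_name = allele$name)
  paths <- c(
    proteome = file.path(dir, "proteome.fasta"),
    expression = file.path(dir, "expression.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    truth = file.path(dir, "truth.tsv"),
    alleles = file.path(dir, "alleles.tsv"),
    pssm = file.path(dir, "pssm.tsv"),
    epitopes = file.path(dir, "epitopes.tsv"))
  write_fasta(prot$proteome, paths[["proteome"]])
  write_tsv_plain(prot$expression, paths[["expression"]])
  write_tsv_plain(prot$orthologs, paths[["orthologs"]])
  write_tsv_plain(prot$truth, paths[["truth"]])
  write_allele_tsv(list(allele), paths[["alleles"]])
  write_pssm(pssm, paths[["pssm"]])
  write_tsv_plain(epi, paths[["epitopes"]])
  invisible(paths)
}
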