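# Binder prediction: PSSM construction from epitope sets, log-odds peptide
# scoring, background percentile ranks, and IC50 binder calls.

#' Construct a PSSM from per-position frequencies
#'
#' Entries are log2-odds against the background composition; cells whose
#' frequency is zero are floored at `floor` bits (keeps arithmetic finite
#' while dominating any realistic score).
#'
#' @param freqs L x 20 matrix of per-position residue frequencies (columns
#'   named by the canonical one-letter codes); each row must sum to 1.
#' @param background Named per-residue background frequency vector (default
#'   uniform 0.05).
#' @param alpha Pseudocount recorded for provenance (default `NA`).
#' @param floor Log-odds floor in bits for zero-frequency cells.
#' @return A `pssm` with fields `length`, `matrix` (log2-odds), `freqs`,
#'   `alpha`, `background`, `floor`.
#' @export
new_pssm <- function(freqs, background = uniform_background(), alpha = NA_real_,
                     floor = -20) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 20 || !identical(colnames(freqs), AA_ALPHABET)) {
    freqs <- freqs[, AA_ALPHABET, drop = FALSE]
  }
  rs <- rowSums(freqs)
  if (any(abs(rs - 1) > 1e-9)) as_error("each PSSM row's frequencies must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) as_error("background frequencies must sum to 1")
  m <- log2(sweep(freqs, 2, background[AA_ALPHABET], "/"))
  m[!is.finite(m)] <- floor
  m <- pmax(m, floor)
  structure(list(length = nrow(freqs), matrix = unname(m), freqs = unname(freqs),
                 alpha = alpha, background = background[AA_ALPHABET], floor = floor),
            class = "pssm")
}

#' Uniform amino-acid background composition
#'
#' @return Named numeric vector, 0.05 per residue.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
}

#' Estimate a PSSM from an epitope set
#'
#' Column frequency is `(count + alpha) / (n + 20 * alpha)` (Laplace
#' pseudocount by default); entries are log2-odds against the background.
#'
#' @param sequences Character vector of equal-length binder sequences.
#' @param alpha Pseudocount (default 1).
#' @param background Per-residue background (default uniform 0.05).
#' @param floor Log-odds floor in bits for zero-frequency cells.
#' @return A [pssm][new_pssm()].
#' @export
pssm_from_epitopes <- function(sequences, alpha = 1, background = uniform_background(),
                               floor = -20) {
  if (length(sequences) < 1) as_error("need at least one sequence")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    as_error("mixed sequence lengths (%s); PSSM estimation needs one length",
             paste(sort(unique(lens)), collapse = ", "))
  }
  L <- lens[1]
  n <- length(sequences)
  chars <- matrix(unlist(strsplit(sequences, "")), nrow = n, byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), AA_ALPHABET)
  if (length(bad) > 0) as_error("non-canonical residue '%s' in epitope set", bad[1])
  freqs <- t(vapply(seq_len(L), function(i) {
    counts <- table(factor(chars[, i], levels = AA_ALPHABET))
    (as.numeric(counts) + alpha) / (n + 20 * alpha)
  }, numeric(20)))
  colnames(freqs) <- AA_ALPHABET
  new_pssm(freqs, background = background, alpha = alpha, floor = floor)
}

# Map sequences to an n x L integer matrix of alphabet indices.
seq_index_matrix <- function(sequences, L) {
  idx <- match(unlist(strsplit(sequences, "")), AA_ALPHABET)
  if (anyNA(idx)) as_error("non-canonical residue in sequence set")
  matrix(idx, ncol = L, byrow = TRUE)
}

#' Score a peptide against a PSSM
#'
#' Sum over positions of the log2-odds entries for the peptide's residues.
#'
#' @param p A sequence string or `peptide`.
#' @param pssm A [pssm][new_pssm()].
#' @return Log2-odds score.
#' @export
score_peptide <- function(p, pssm) {
  seqs <- if (inherits(p, "peptide")) p$sequence else p
  stopifnot(inherits(pssm, "pssm"))
  if (any(nchar(seqs) != pssm$length)) {
    as_error("peptide length %d does not match PSSM length %d",
             nchar(seqs)[1], pssm$length)
  }
  idx <- seq_index_matrix(seqs, pssm$length)
  pos <- matrix(rep(seq_len(pssm$length), each = nrow(idx)), nrow = nrow(idx))
  scores <- rowSums(matrix(pssm$matrix[cbind(as.vector(pos), as.vector(idx))],
                           nrow = nrow(idx)))
  if (length(seqs) == 1) scores[[1]] else scores
}

#' Seeded background score distribution for percentile ranks
#'
#' Scores of `n` i.i.d. uniform-composition peptides of the PSSM's length;
#' the empirical reference against which a query's percentile rank is
#' computed.
#'
#' @param pssm A [pssm][new_pssm()].
#' @param n Background sample size (default 100000).
#' @param seed Integer seed.
#' @return Numeric score vector of length `n`.
#' @export
background_scores <- function(pssm, n = 100000, seed = 1) {
  stopifnot(inherits(pssm, "pssm"))
  with_stream_seed(seed, "background", {
    idx <- matrix(sample.int(20, n * pssm$length, replace = TRUE), ncol = pssm$length)
    pos <- matrix(rep(seq_len(pssm$length), each = n), nrow = n)
    rowSums(matrix(pssm$matrix[cbind(as.vector(pos), as.vector(idx))], nrow = n))
  })
}

#' Percentile rank of a score against a background
#'
#' `rank = 100 * #{b in background : b >= score} / N`; small ranks denote
#' strong predicted binders. Vectorized over `score`.
#'
#' @param score Numeric score(s).
#' @param background Non-empty numeric background score vector.
#' @return Rank(s) in \[0, 100\].
#' @export
percentile_rank <- function(score, background) {
  if (length(background) == 0) as_error("background score set must be non-empty")
  sb <- sort(background)
  n_lt <- findInterval(score, sb, left.open = TRUE)
  100 * (length(sb) - n_lt) / length(sb)
}

#' Strong-binder call from a percentile rank
#'
#' @param rank Percentile rank(s) in \[0, 100\].
#' @param strong_threshold Maximum rank called strong (default 0.5, a
#'   configurable stand-in for the external predictor's strong-binder
#'   cutoff).
#' @return Logical vector.
#' @export
is_strong_binder <- function(rank, strong_threshold = 0.5) {
  rank <= strong_threshold
}

#' Classify epitopes as binders or nonbinders by IC50
#'
#' Binder iff IC50 is at most the threshold (inclusive at 500 nM).
#'
#' @param ic50_nm Positive IC50 value(s) in nM; `NA` is an error.
#' @param threshold_nm Affinity threshold (default 500).
#' @return Character vector of `"binder"` / `"nonbinder"`.
#' @export
classify_binder <- function(ic50_nm, threshold_nm = 500) {
  if (anyNA(ic50_nm)) as_error("ic50_nm missing; cannot classify")
  if (any(ic50_nm <= 0)) as_error("ic50_nm must be positive")
  ifelse(ic50_nm <= threshold_nm, "binder", "nonbinder")
}

#' Write a PSSM as a square-matrix text file
#'
#' Header row of residue letters, one row per position.
#'
#' @param pssm A [pssm][new_pssm()].
#' @param path Output path.
#' @export
write_pssm <- function(pssm, path) {
  m <- pssm$matrix
  lines <- c(paste(AA_ALPHABET, collapse = "\t"),
             apply(m, 1, function(r) paste(fmt_num(r), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PSSM written by [write_pssm()]
#'
#' The reconstructed object carries log-odds entries and frequencies implied
#' by inverting the log-odds against a uniform background.
#'
#' @param path File path.
#' @param background Background composition used to invert entries.
#' @return A [pssm][new_pssm()].
#' @export
read_pssm <- function(path, background = uniform_background()) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df)[, AA_ALPHABET, drop = FALSE]
  freqs <- sweep(2^m, 2, background[AA_ALPHABET], "*")
  freqs <- freqs / rowSums(freqs)
  p <- new_pssm(freqs, background = background)
  p$matrix <- unname(m)  # preserve floored cells exactly
  p
}
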