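# Independent oracles and fixture builders shared across tests.

# Brute-force template selection: score every same-length entry with an
# explicit residue-by-residue loop, take the max, break ties by smallest id.
brute_select_template <- function(query, lib, matrix) {
  qc <- strsplit(query, "")[[1]]
  best_score <- -Inf
  best_id <- NULL
  ids <- sort(names(lib), method = "radix")
  for (id in ids) {
    e <- lib[[id]]
    if (nchar(e$peptide_sequence) != length(qc)) next
    tc <- strsplit(e$peptide_sequence, "")[[1]]
    s <- 0
    for (i in seq_along(qc)) s <- s + matrix[qc[i], tc[i]]
    if (s > best_score) {
      best_score <- s
      best_id <- id
    }
  }
  list(id = best_id, score = best_score)
}

# Full-enumeration Mann-Whitney oracle: U (ties 1/2) for every choose(N, nA)
# labeling, tails inclusive, two-sided by doubling the smaller tail.
brute_ranksum <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(U = u_obs,
       p_ge = mean(us >= u_obs - 1e-12),
       p_le = mean(us <= u_obs + 1e-12),
       p_two = min(1, 2 * min(mean(us >= u_obs - 1e-12), mean(us <= u_obs + 1e-12))))
}

# Random same-length template library; entries `tie_pair` share a sequence
# so the lexicographic tie-break is exercised.
random_library <- function(n = 20, len = 9, tie_pair = TRUE) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(adductscan:::AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
  if (tie_pair && n >= 2) seqs[n] <- seqs[n - 1]
  ids <- sprintf("T%02d", sample.int(n))
  template_library(lapply(seq_len(n), function(i) {
    template_entry(ids[i], seqs[i], matrix(stats::rnorm(len * 3), ncol = 3))
  }))
}

# Minimal one-complex PDB text: 9-residue peptide on chain C plus a few
# receptor CA pseudo-atoms on chain A.
write_test_pdb <- function(path, peptide = "LAGKNLTHI", chain = "C",
                           drop_ca_at = NULL, altloc_at = NULL) {
  three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
             E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
             M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
             Y = "TYR", V = "VAL")
  lines <- character(0)
  serial <- 1
  fmt <- function(serial, name, alt, res, ch, seqno, x, y, z) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, paste0(" ", name), alt, res, ch, seqno, x, y, z)
  }
  for (i in seq_len(nchar(peptide))) {
    res <- three[substr(peptide, i, i)]
    alt <- if (!is.null(altloc_at) && i == altloc_at) "A" else " "
    if (is.null(drop_ca_at) || i != drop_ca_at) {
      lines <- c(lines, fmt(serial, "CA", alt, res, chain, i, i * 3.8, 0, 0))
      serial <- serial + 1
    }
    lines <- c(lines, fmt(serial, "CB", " ", res, chain, i, i * 3.8, 1.5, 0))
    serial <- serial + 1
  }
  for (j in 1:4) {
    lines <- c(lines, fmt(serial, "CA", " ", "GLY", "A", j, j * 3.8, 5, 2))
    serial <- serial + 1
  }
  writeLines(c(lines, "END"), path)
  path
}

# Post-hoc audit of the three screening predicates, computed independently
# of screen_candidates' internals.
audit_candidate <- function(rec, expression, orthologs, pssm, favorable, config) {
  src <- orthologs$from[orthologs$to == rec$protein]
  folds <- vapply(src, function(h) {
    sub <- expression[expression$protein == h, ]
    tgt <- sub$expression[sub$tissue == config$target_tissue]
    others <- sub$expression[sub$tissue != config$target_tissue]
    if (max(others) == 0) {
      if (tgt > 0) Inf else 0
    } else {
      tgt / max(others)
    }
  }, numeric(1))
  pass_expr <- any(folds > config$fold_threshold)
  bg <- background_scores(pssm, n = config$background_n, seed = config$seed)
  rank <- 100 * sum(bg >= score_peptide(rec$peptide, pssm)) / length(bg)
  pass_binder <- rank <= config$rank_threshold
  kpos <- which(strsplit(rec$peptide, "")[[1]] == "K")
  pass_lys <- any(kpos %in% favorable)
  pass_expr && pass_binder && pass_lys
}
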