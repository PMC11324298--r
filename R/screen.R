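# The candidate-screening chain: tissue-overexpression filter, ortholog
# mapping, k-mer enumeration, strong-binder filter, favorable-lysine filter,
# deduplication; plus the HLA allele-frequency panel selection rule.

#' Screening configuration
#'
#' @param target_tissue Tissue whose overexpression defines the source-set
#'   filter (default `"kidney"`).
#' @param fold_threshold Required fold change, strict inequality (default 4:
#'   greater than 4-fold).
#' @param denominator `"max"` (default; conservative, matches the
#'   tissue-enriched convention) or `"mean"` over non-target tissues.
#' @param rank_threshold Strong-binder percentile-rank cutoff (default 0.5).
#' @param k Peptide length enumerated from source proteins (default 9).
#' @param background_n Background sample size for percentile ranks (default
#'   100000).
#' @param seed Seed for the background sample (the only stochastic step).
#' @return A `screen_config` list.
#' @export
screen_config <- function(target_tissue = "kidney", fold_threshold = 4,
                          denominator = c("max", "mean"), rank_threshold = 0.5,
                          k = 9, background_n = 100000, seed = 1) {
  structure(list(target_tissue = target_tissue, fold_threshold = fold_threshold,
                 denominator = match.arg(denominator),
                 rank_threshold = rank_threshold, k = as.integer(k),
                 background_n = as.integer(background_n), seed = as.integer(seed)),
            class = "screen_config")
}

#' Filter proteins overexpressed in a target tissue
#'
#' Keeps a protein iff `level(target) / denominator > fold_threshold`
#' (strict), where the denominator is the max (default) or mean of its
#' levels in all other tissues. A zero denominator with positive target
#' level counts as infinite fold (kept). Proteins missing the target-tissue
#' row are excluded with a warning, not fatally.
#'
#' @param expression Expression data frame (`protein`, `tissue`,
#'   `expression`).
#' @param target_tissue Target tissue name.
#' @param fold_threshold Strict fold cutoff (default 4).
#' @param denominator `"max"` or `"mean"`.
#' @return Data frame (`protein`, `fold_change`, `pass`), one row per
#'   evaluable protein, ordered by protein id.
#' @export
filter_overexpressed <- function(expression, target_tissue = "kidney",
                                 fold_threshold = 4,
                                 denominator = c("max", "mean")) {
  denominator <- match.arg(denominator)
  proteins <- sort(unique(expression$protein), method = "radix")
  rows <- lapply(proteins, function(pr) {
    sub <- expression[expression$protein == pr, , drop = FALSE]
    tgt <- sub$expression[sub$tissue == target_tissue]
    if (length(tgt) == 0) {
      warning(sprintf("protein '%s' has no '%s' row; excluded from the expression filter",
                      pr, target_tissue), call. = FALSE)
      return(NULL)
    }
    others <- sub$expression[sub$tissue != target_tissue]
    den <- if (length(others) == 0) 0 else switch(denominator,
                                                  max = max(others),
                                                  mean = mean(others))
    fold <- if (den == 0) {
      if (tgt > 0) Inf else 0
    } else {
      tgt / den
    }
    data.frame(protein = pr, fold_change = fold,
               pass = fold > fold_threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein = character(0), fold_change = numeric(0),
                      pass = logical(0))
  }
  out
}

#' Map protein ids through an ortholog table
#'
#' Unmapped ids are reported, never silently dropped; many-to-one mappings
#' are deduplicated.
#'
#' @param ids Character vector of source ids.
#' @param orthologs Data frame with columns `from`, `to`.
#' @return List with `mapped` (unique target ids, in first-occurrence
#'   order), `dropped` (unmapped source ids) and `map` (the used rows).
#' @export
map_orthologs <- function(ids, orthologs) {
  hit <- orthologs[orthologs$from %in% ids, , drop = FALSE]
  dropped <- setdiff(ids, hit$from)
  list(mapped = unique(hit$to), dropped = dropped, map = hit)
}

#' Enumerate k-mers of a protein sequence
#'
#' All `L - k + 1` windows in order with their 1-based start offsets; a
#' protein shorter than `k` yields zero rows.
#'
#' @param sequence Protein sequence string.
#' @param k Window length (default 9).
#' @return Data frame (`start`, `peptide`).
#' @export
enumerate_kmers <- function(sequence, k = 9) {
  k <- as.integer(k)
  if (k < 1) as_error("k must be >= 1")
  L <- nchar(sequence)
  if (L < k) return(data.frame(start = integer(0), peptide = character(0)))
  starts <- seq_len(L - k + 1)
  data.frame(start = starts,
             peptide = substring(sequence, starts, starts + k - 1),
             stringsAsFactors = FALSE)
}

#' Run the full candidate-screening pipeline
#'
#' Chain: tissue-overexpression filter -> ortholog mapping -> k-mer
#' enumeration -> strong-binder filter (PSSM percentile rank against a
#' seeded uniform background) -> lysine-at-favorable-position filter ->
#' global sequence dedup (first occurrence wins, ordered by protein id then
#' offset). Every emitted record carries per-filter pass flags; the run is
#' fully deterministic given the config (the seed only affects the
#' background score sample). Per-filter counts are logged via `message()`.
#'
#' @param proteome Named character vector of protein sequences (ids match
#'   the ortholog table's `to` column), or a FASTA path.
#' @param expression Expression data frame (or TSV path).
#' @param orthologs Ortholog data frame (or TSV path).
#' @param allele An `allele_model` (used for provenance and length checks).
#' @param pssm A [pssm][new_pssm()] of length `config$k`.
#' @param favorable Non-empty integer set of favorable lysine positions.
#' @param config A [screen_config()].
#' @return A `candidate_table` data frame with columns `protein`, `start`,
#'   `peptide`, `lysine_positions`, `fold_change`, `binder_rank`,
#'   `pass_expression`, `pass_binder`, `pass_lysine`, `pass_all`.
#' @export
screen_candidates <- function(proteome, expression, orthologs, allele, pssm,
                              favorable, config = screen_config()) {
  if (is.character(proteome) && length(proteome) == 1 && file.exists(proteome)) {
    proteome <- read_fasta(proteome)
  }
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  if (is.character(orthologs)) orthologs <- read_ortholog_tsv(orthologs)
  if (length(proteome) == 0) as_error("proteome is empty")
  if (length(favorable) == 0) as_error("favorable position set must be non-empty")
  if (pssm$length != config$k) {
    as_error("PSSM length %d does not match k = %d", pssm$length, config$k)
  }
  if (!(config$k %in% allele$supported_lengths)) {
    as_error("allele '%s' does not support length %d", allele$name, config$k)
  }

  expr <- filter_overexpressed(expression, config$target_tissue,
                               config$fold_threshold, config$denominator)
  kept <- expr[expr$pass, , drop = FALSE]
  message(sprintf("expression filter: %d/%d proteins > %g-fold in %s",
                  nrow(kept), nrow(expr), config$fold_threshold, config$target_tissue))

  om <- map_orthologs(kept$protein, orthologs)
  if (length(om$dropped) > 0) {
    message(sprintf("ortholog mapping: no homolog for %s",
                    paste(om$dropped, collapse = ", ")))
  }
  # fold change carried over: max across source proteins mapping to a target
  fold_by_target <- vapply(om$mapped, function(t) {
    max(kept$fold_change[kept$protein %in% om$map$from[om$map$to == t]])
  }, numeric(1))
  targets <- sort(om$mapped, method = "radix")
  missing_seq <- setdiff(targets, names(proteome))
  if (length(missing_seq) > 0) {
    message(sprintf("no sequence in proteome for %s", paste(missing_seq, collapse = ", ")))
    targets <- setdiff(targets, missing_seq)
  }
  message(sprintf("ortholog mapping: %d target proteins", length(targets)))

  bg <- background_scores(pssm, n = config$background_n, seed = config$seed)

  records <- lapply(targets, function(t) {
    km <- enumerate_kmers(proteome[[t]], config$k)
    if (nrow(km) == 0) return(NULL)
    km$protein <- t
    km$fold_change <- fold_by_target[[t]]
    km
  })
  records <- do.call(rbind, records)
  if (is.null(records) || nrow(records) == 0) {
    message("k-mer enumeration: 0 windows")
    return(empty_candidate_table())
  }
  records <- records[order(records$protein, records$start, method = "radix"), ]
  message(sprintf("k-mer enumeration: %d windows", nrow(records)))

  scores <- score_peptide(records$peptide, pssm)
  records$binder_rank <- percentile_rank(scores, bg)
  records$pass_binder <- is_strong_binder(records$binder_rank, config$rank_threshold)
  message(sprintf("strong-binder filter: %d windows at rank <= %g",
                  sum(records$pass_binder), config$rank_threshold))

  kpos <- lapply(records$peptide, function(s) which(strsplit(s, "")[[1]] == "K"))
  records$lysine_positions <- vapply(kpos, function(v) paste(v, collapse = ","), character(1))
  records$pass_lysine <- vapply(kpos, function(v) any(v %in% favorable), logical(1))
  message(sprintf("favorable-lysine filter: %d windows with K at {%s}",
                  sum(records$pass_lysine), paste(sort(favorable), collapse = ",")))

  records$pass_expression <- TRUE   # only overexpressed, mapped proteins reach here
  dup <- duplicated(records$peptide)
  records <- records[!dup, , drop = FALSE]
  records$pass_all <- records$pass_expression & records$pass_binder & records$pass_lysine
  message(sprintf("dedup: %d unique peptides, %d fully passing",
                  nrow(records), sum(records$pass_all)))

  out <- records[, c("protein", "start", "peptide", "lysine_positions",
                     "fold_change", "binder_rank", "pass_expression",
                     "pass_binder", "pass_lysine", "pass_all")]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

empty_candidate_table <- function() {
  out <- data.frame(protein = character(0), start = integer(0),
                    peptide = character(0), lysine_positions = character(0),
                    fold_change = numeric(0), binder_rank = numeric(0),
                    pass_expression = logical(0), pass_binder = logical(0),
                    pass_lysine = logical(0), pass_all = logical(0))
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Write a candidate table as TSV
#'
#' Byte-deterministic formatting (fixed-precision numerics).
#'
#' @param ct A `candidate_table`.
#' @param path Output path.
#' @export
write_candidate_tsv <- function(ct, path) {
  df <- as.data.frame(ct)
  df$fold_change <- fmt_num(df$fold_change, 4)
  df$binder_rank <- fmt_num(df$binder_rank, 4)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select an HLA allele panel from phenotype frequencies
#'
#' Per population, takes the `top_n` alleles by phenotype frequency among
#' those with frequency strictly above `min_freq`; the union across
#' populations is returned with duplicates collapsed. Ties broken by
#' allele-name lexicographic order; fully deterministic.
#'
#' @param freq Data frame (`population`, `allele`, `frequency`) or TSV path.
#' @param min_freq Minimum phenotype frequency, strict (default 0.05).
#' @param top_n Alleles retained per population (default 10).
#' @return Data frame (`allele`, `populations`, `max_frequency`) sorted by
#'   allele name; `populations` lists the contributing populations.
#' @export
select_hla_alleles <- function(freq, min_freq = 0.05, top_n = 10) {
  if (is.character(freq)) freq <- read_allele_freq_tsv(freq)
  if (length(unique(freq$population)) < 1) as_error("need at least one population")
  picks <- lapply(sort(unique(freq$population), method = "radix"), function(pop) {
    sub <- freq[freq$population == pop & freq$frequency > min_freq, , drop = FALSE]
    sub <- sub[order(-sub$frequency, sub$allele, method = "radix"), , drop = FALSE]
    utils::head(sub, top_n)
  })
  picks <- do.call(rbind, picks)
  if (is.null(picks) || nrow(picks) == 0) {
    return(data.frame(allele = character(0), populations = character(0),
                      max_frequency = numeric(0)))
  }
  alleles <- sort(unique(picks$allele), method = "radix")
  data.frame(
    allele = alleles,
    populations = vapply(alleles, function(a) {
      paste(sort(picks$population[picks$allele == a], method = "radix"), collapse = ",")
    }, character(1)),
    max_frequency = vapply(alleles, function(a) max(picks$frequency[picks$allele == a]),
                           numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
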