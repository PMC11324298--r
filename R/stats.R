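# Group comparisons (exact Mann-Whitney rank-sum) and per-position
# delta-score aggregation for identifying favorable adduction positions.

# Exact distribution of 2*W_A (doubled midrank sum of group A) over all
# C(N, n_A) labelings, by the shift-algorithm DP over doubled midranks.
# Returns P(2W_A <= w) and P(2W_A >= w) for the observed w.
exact_tails <- function(d2, n_a, w_obs2) {
  total <- sum(d2)
  # f[k+1, s+1] = number of k-subsets of d2 with sum s
  f <- matrix(0, nrow = n_a + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (v in d2) {
    kmax <- min(n_a, nrow(f) - 1)
    for (k in kmax:1) {
      idx <- seq_len(total + 1 - v)
      f[k + 1, idx + v] <- f[k + 1, idx + v] + f[k, idx]
    }
  }
  counts <- f[n_a + 1, ]
  sums <- 0:total
  n_comb <- sum(counts)
  list(p_le = sum(counts[sums <= w_obs2]) / n_comb,
       p_ge = sum(counts[sums >= w_obs2]) / n_comb)
}

#' Mann-Whitney rank-sum comparison of two score groups
#'
#' U counts A-over-B pairs with ties counted 1/2. For small groups (both
#' sizes at most 8) the p-value is exact over all `choose(nA+nB, nA)`
#' labelings (shift-algorithm DP over doubled midranks, so ties are handled
#' exactly); otherwise the tie-corrected normal approximation is used (no
#' continuity correction). The two-sided p doubles the smaller tail, capped
#' at 1.
#'
#' @param a,b Non-empty numeric score vectors.
#' @param mode `"auto"` (exact iff both sizes <= 8), `"exact"`, or
#'   `"normal"`.
#' @return A `ranksum_result`: `U`, `p_two_sided`, `p_greater` (upper tail,
#'   P(U >= u)), `p_less`, `method`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) as_error("both score groups must be non-empty")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks
  w_a <- sum(r[seq_len(n_a)])
  u <- w_a - n_a * (n_a + 1) / 2
  exact <- switch(mode, exact = TRUE, normal = FALSE, auto = (n_a <= 8 && n_b <= 8))
  if (exact) {
    d2 <- as.integer(round(2 * r))
    w_obs2 <- as.integer(round(2 * w_a))
    tails <- exact_tails(d2, n_a, w_obs2)
    p_ge <- tails$p_ge; p_le <- tails$p_le
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    n <- n_a + n_b
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- n_a * n_b / 12 * (n + 1 - tie_term)
    if (s2 <= 0) {
      p_ge <- 1; p_le <- 1
    } else {
      z <- (u - mu) / sqrt(s2)
      p_ge <- stats::pnorm(z, lower.tail = FALSE)
      p_le <- stats::pnorm(z, lower.tail = TRUE)
    }
    method <- "normal-approximation"
  }
  structure(list(U = u, p_two_sided = min(1, 2 * min(p_ge, p_le)),
                 p_greater = p_ge, p_less = p_le,
                 method = method, n_a = n_a, n_b = n_b),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("<ranksum_result> U=%.1f p(two-sided)=%.4g [%s, n=%d vs %d]\n",
              x$U, x$p_two_sided, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Assemble a delta-score table
#'
#' One row per (peptide, lysine position) pair with its adduction delta
#' score. Anchor positions are excluded here, upstream of any aggregation
#' (per-residue analysis covers non-anchoring residues only); a row at an
#' anchor position is an error.
#'
#' @param peptide_id Character vector of peptide identifiers.
#' @param position Integer 1-based lysine positions.
#' @param delta Numeric delta scores.
#' @param allele Allele name (recycled).
#' @param anchor_positions Integer set of excluded anchors.
#' @return A `delta_table` data frame with an `anchors` attribute.
#' @export
delta_table <- function(peptide_id, position, delta, allele = NA_character_,
                        anchor_positions = integer(0)) {
  position <- as.integer(position)
  if (any(position %in% anchor_positions)) {
    as_error("delta table contains anchor position %d; anchors are excluded upstream",
             intersect(position, anchor_positions)[1])
  }
  df <- data.frame(peptide_id = as.character(peptide_id), position = position,
                   delta = as.numeric(delta),
                   allele = rep_len(as.character(allele), length(position)),
                   stringsAsFactors = FALSE)
  attr(df, "anchors") <- as.integer(anchor_positions)
  class(df) <- c("delta_table", "data.frame")
  df
}

#' Compute a delta table for a set of peptides against one allele
#'
#' Adducts each non-anchor lysine of each peptide in silico and records the
#' resulting delta score.
#'
#' @param peptides Named list of `peptide` objects (or character vector of
#'   sequences; names become peptide ids).
#' @param allele An `allele_model` with a PSSM.
#' @param species Adduct species name (default `"pyrrole"`).
#' @param params [surrogate_params()].
#' @param backend Backend name.
#' @param registry Adduct registry.
#' @return A [delta_table()].
#' @export
build_delta_table <- function(peptides, allele, species = "pyrrole",
                              params = surrogate_params(), backend = "surrogate",
                              registry = default_adduct_registry()) {
  if (is.character(peptides)) {
    nms <- names(peptides) %||% paste0("pep", seq_along(peptides))
    peptides <- stats::setNames(lapply(peptides, parse_peptide), nms)
  }
  L <- nchar(peptides[[1]]$sequence)
  anchors <- allele$anchors[[as.character(L)]]
  ids <- character(0); pos <- integer(0); dl <- numeric(0)
  for (nm in names(peptides)) {
    p <- peptides[[nm]]
    ks <- setdiff(lysine_positions(p), anchors)
    for (i in ks) {
      d <- delta_score(complex_model(p), i, species, allele, params, backend, registry)
      ids <- c(ids, nm); pos <- c(pos, i); dl <- c(dl, d)
    }
  }
  delta_table(ids, pos, dl, allele = allele$name, anchor_positions = anchors)
}

#' Per-position delta-score summary
#'
#' For each observed position: number of observations, mean delta, and the
#' count of observations with delta at most `tau`. Positions with no
#' observations are absent, not zero-filled.
#'
#' @param dt A [delta_table()].
#' @param tau Favorability threshold on delta (default 0: no score increase
#'   after adduction).
#' @return Data frame (`position`, `n`, `mean_delta`, `n_favorable`) sorted
#'   by position, with attributes `tau` and `anchors`.
#' @export
per_position_delta <- function(dt, tau = 0) {
  if (nrow(dt) == 0) {
    out <- data.frame(position = integer(0), n = integer(0),
                      mean_delta = numeric(0), n_favorable = integer(0))
  } else {
    positions <- sort(unique(dt$position))
    out <- do.call(rbind, lapply(positions, function(p) {
      d <- dt$delta[dt$position == p]
      data.frame(position = p, n = length(d), mean_delta = mean(d),
                 n_favorable = sum(d <= tau))
    }))
  }
  attr(out, "tau") <- tau
  attr(out, "anchors") <- attr(dt, "anchors")
  out
}

#' Identify favorable adduction positions
#'
#' A position is favorable when at least `m` peptides show delta at most
#' `tau` there (multiple modeled peptides with no score increase after
#' adduction). Also reports the ranking of positions by ascending mean
#' delta.
#'
#' @param summary Output of [per_position_delta()].
#' @param tau Threshold; must match the `tau` the summary was built with.
#' @param m Minimum count of favorable peptides (default 2).
#' @return List with `positions` (ascending integer vector) and `ranking`
#'   (all observed positions ordered by mean delta).
#' @export
favorable_positions <- function(summary, tau = 0, m = 2) {
  stopifnot(!is.null(summary$n_favorable))
  stau <- attr(summary, "tau")
  if (!is.null(stau) && !isTRUE(all.equal(stau, tau))) {
    as_error("summary was built with tau = %g; rebuild with per_position_delta(dt, tau = %g)",
             stau, tau)
  }
  ord <- order(summary$mean_delta, summary$position)
  list(positions = sort(summary$position[summary$n_favorable >= m]),
       ranking = summary$position[ord])
}

#' Write / read a delta table as TSV
#'
#' @param dt A [delta_table()].
#' @param path File path.
#' @export
write_delta_tsv <- function(dt, path) {
  df <- as.data.frame(dt)
  attr(df, "anchors") <- NULL
  write_tsv_plain(df, path)
}

#' @rdname write_delta_tsv
#' @param anchor_positions Anchor set to validate against on read.
#' @export
read_delta_tsv <- function(path, anchor_positions = integer(0)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  delta_table(df$peptide_id, df$position, df$delta,
              allele = df$allele %||% NA_character_,
              anchor_positions = anchor_positions)
}
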