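# Candidate screening chain and HLA panel selection.

test_that("overexpression filter uses a strict fold boundary and max denominator", {
  expr <- data.frame(
    protein = rep(c("P1", "P2", "P3"), each = 3),
    tissue = rep(c("kidney", "liver", "lung"), 3),
    expression = c(40, 9, 8,     # fold 40/9 > 4 -> kept
                   40, 10, 9,    # fold exactly 4 -> dropped (strictly greater)
                   5, 0, 0))     # zero denominator, positive target -> kept
  out <- filter_overexpressed(expr, "kidney", 4)
  expect_equal(out$pass, c(TRUE, FALSE, TRUE))
  expect_equal(out$fold_change[1], 40 / 9, tolerance = 1e-12)
  expect_equal(out$fold_change[2], 4)
  expect_true(is.infinite(out$fold_change[3]))
})

test_that("proteins missing the target tissue are excluded with a warning", {
  expr <- data.frame(protein = c("P1", "P1", "P2"),
                     tissue = c("kidney", "liver", "liver"),
                     expression = c(50, 5, 5))
  expect_warning(out <- filter_overexpressed(expr, "kidney"), "P2")
  expect_equal(out$protein, "P1")
})

test_that("ortholog mapping reports dropped ids and deduplicates targets", {
  tab <- data.frame(from = c("H1", "H3"), to = c("m1", "m1"))
  r1 <- map_orthologs(c("H1", "H2"), tab)
  expect_equal(r1$mapped, "m1")
  expect_equal(r1$dropped, "H2")
  r2 <- map_orthologs(c("H1", "H3"), tab)
  expect_equal(r2$mapped, "m1")         # many-to-one collapsed
  r3 <- map_orthologs(c("H1", "H2"), tab[0, ])
  expect_equal(r3$mapped, character(0))
  expect_equal(r3$dropped, c("H1", "H2"))
})

test_that("k-mer enumeration emits every window with 1-based offsets", {
  expect_equal(enumerate_kmers(strrep("A", 9), 9),
               data.frame(start = 1L, peptide = strrep("A", 9)))
  km <- enumerate_kmers("ABCDEFGHIJK", 9)   # length 11 -> 3 windows
  expect_equal(km$start, 1:3)
  expect_equal(km$peptide[2], "BCDEFGHIJ")
  expect_equal(nrow(enumerate_kmers(strrep("A", 8), 9)), 0)
})

test_that("the planted synthetic instance is recovered exactly", {
  spec <- plant_spec(seed = 42, n_proteins = 5)
  pssm <- gen_pssm(spec)
  allele <- gen_allele(spec, pssm)
  fx <- gen_proteome(spec, pssm)
  cfg <- screen_config(seed = 42, background_n = 20000)
  ct <- suppressMessages(screen_candidates(fx$proteome, fx$expression, fx$orthologs,
                                           allele, pssm, spec$favorable, cfg))
  hits <- ct[ct$pass_all, ]
  expect_equal(sort(hits$peptide), sort(fx$truth$peptide))
  expect_equal(hits$start, fx$truth$start)
  expect_equal(sort(hits$protein), sort(fx$truth$protein))
  # subset conservation: output windows come from enumerated k-mers of
  # mapped, overexpressed proteins
  for (i in seq_len(nrow(ct))) {
    km <- enumerate_kmers(fx$proteome[[ct$protein[i]]], 9)
    expect_true(ct$peptide[i] %in% km$peptide)
  }
  # post-hoc audit: every fully-passing record satisfies all predicates
  for (i in which(ct$pass_all)) {
    expect_true(audit_candidate(ct[i, ], fx$expression, fx$orthologs,
                                pssm, spec$favorable, cfg))
  }
  # and no non-passing record does
  for (i in which(!ct$pass_all)) {
    expect_false(audit_candidate(ct[i, ], fx$expression, fx$orthologs,
                                 pssm, spec$favorable, cfg))
  }
})

test_that("screening is idempotent on its own output proteome subset", {
  spec <- plant_spec(seed = 7)
  pssm <- gen_pssm(spec)
  allele <- gen_allele(spec, pssm)
  fx <- gen_proteome(spec, pssm)
  cfg <- screen_config(seed = 7, background_n = 20000)
  ct1 <- suppressMessages(screen_candidates(fx$proteome, fx$expression, fx$orthologs,
                                            allele, pssm, spec$favorable, cfg))
  sub <- fx$proteome[unique(ct1$protein)]
  ct2 <- suppressMessages(screen_candidates(sub, fx$expression, fx$orthologs,
                                            allele, pssm, spec$favorable, cfg))
  expect_equal(ct1, ct2)
})

test_that("a lysine-free source set yields zero fully passing candidates", {
  spec <- plant_spec(seed = 3, n_planted = 0, n_proteins = 4)
  pssm <- gen_pssm(spec)
  allele <- gen_allele(spec, pssm)
  # one overexpressed lysine-free protein
  proteome <- c(MMP001 = paste(rep("ADEF", 15), collapse = ""))
  expr <- data.frame(protein = rep("HSP001", 2), tissue = c("kidney", "liver"),
                     expression = c(50, 5))
  ortho <- data.frame(from = "HSP001", to = "MMP001")
  ct <- suppressMessages(screen_candidates(proteome, expr, ortho, allele, pssm,
                                           spec$favorable,
                                           screen_config(seed = 3, background_n = 5000)))
  expect_equal(sum(ct$pass_all), 0)
  expect_true(all(!ct$pass_lysine))
})

test_that("a zero rank threshold admits only background-beating scores", {
  spec <- plant_spec(seed = 4, n_planted = 0, n_proteins = 4)
  pssm <- gen_pssm(spec)
  allele <- gen_allele(spec, pssm)
  # random overexpressed protein: no window outscores the whole background
  set.seed(4)
  proteome <- c(MMP001 = paste(sample(adductscan:::AA_ALPHABET, 60, replace = TRUE),
                               collapse = ""))
  expr <- data.frame(protein = rep("HSP001", 2), tissue = c("kidney", "liver"),
                     expression = c(50, 5))
  ortho <- data.frame(from = "HSP001", to = "MMP001")
  cfg <- screen_config(seed = 4, background_n = 50000, rank_threshold = 0)
  ct <- suppressMessages(screen_candidates(proteome, expr, ortho, allele, pssm,
                                           spec$favorable, cfg))
  expect_equal(sum(ct$pass_all), 0)
})

test_that("candidate tables are written byte-identically for a fixed seed", {
  spec <- plant_spec(seed = 11)
  pssm <- gen_pssm(spec)
  allele <- gen_allele(spec, pssm)
  fx <- gen_proteome(spec, pssm)
  cfg <- screen_config(seed = 11, background_n = 20000)
  f1 <- tempfile(); f2 <- tempfile()
  ct1 <- suppressMessages(screen_candidates(fx$proteome, fx$expression, fx$orthologs,
                                            allele, pssm, spec$favorable, cfg))
  ct2 <- suppressMessages(screen_candidates(fx$proteome, fx$expression, fx$orthologs,
                                            allele, pssm, spec$favorable, cfg))
  write_candidate_tsv(ct1, f1)
  write_candidate_tsv(ct2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("HLA panel selection unions per-population top lists", {
  freq <- data.frame(
    population = c(rep("pop1", 2), rep("pop2", 2)),
    allele = c("A*02:01", "B*07:02", "A*02:01", "C*04:01"),
    frequency = c(0.45, 0.15, 0.40, 0.12))
  panel <- select_hla_alleles(freq, min_freq = 0.05, top_n = 10)
  expect_equal(panel$allele, c("A*02:01", "B*07:02", "C*04:01"))  # 3 after dedup
  expect_equal(panel$populations[panel$allele == "A*02:01"], "pop1,pop2")
  # min_freq = 1 excludes everything
  expect_equal(nrow(select_hla_alleles(freq, min_freq = 1)), 0)
})

test_that("HLA selection truncates to top_n per population by frequency", {
  freq <- data.frame(population = "pop1",
                     allele = sprintf("A*%02d:01", 1:12),
                     frequency = seq(0.30, 0.08, length.out = 12))
  panel <- select_hla_alleles(freq, min_freq = 0.05, top_n = 10)
  expect_equal(nrow(panel), 10)
  expect_false(any(sprintf("A*%02d:01", 11:12) %in% panel$allele))
  # strict min_freq boundary
  freq2 <- data.frame(population = "p", allele = c("X", "Y"),
                      frequency = c(0.05, 0.051))
  expect_equal(select_hla_alleles(freq2, min_freq = 0.05)$allele, "Y")
})

test_that("screen inputs are validated", {
  spec <- plant_spec(seed = 1)
  pssm <- gen_pssm(spec)
  allele <- gen_allele(spec, pssm)
  expr <- data.frame(protein = "H", tissue = "kidney", expression = 1)
  ortho <- data.frame(from = "H", to = "M")
  expect_error(suppressMessages(
    screen_candidates(character(0), expr, ortho, allele, pssm, c(4, 6, 7))),
    "empty")
  expect_error(suppressMessages(
    screen_candidates(c(M = "AAAA"), expr, ortho, allele, pssm, integer(0))),
    "favorable")
  cfg8 <- screen_config(k = 8)
  expect_error(suppressMessages(
    screen_candidates(c(M = "AAAA"), expr, ortho, allele, pssm, c(4, 6), cfg8)),
    "match")
})
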