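# PSSM estimation, log-odds scoring, percentile ranks, binder calls.

test_that("IC50 binder calls use an inclusive 500 nM boundary", {
  expect_equal(classify_binder(500), "binder")
  expect_equal(classify_binder(501), "nonbinder")
  expect_equal(classify_binder(0.1), "binder")
  expect_equal(classify_binder(c(1, 1000)), c("binder", "nonbinder"))
  expect_error(classify_binder(NA_real_), "missing")
  # every record falls in exactly one class
  set.seed(1)
  calls <- classify_binder(10^stats::runif(200, -1, 5))
  expect_true(all(calls %in% c("binder", "nonbinder")))
})

test_that("PSSM estimation applies Laplace smoothing against the background", {
  # two sequences sharing A at position 1: freq = (2+1)/(2+20) = 3/22
  m <- pssm_from_epitopes(c("AC", "AD"), alpha = 1)
  expect_equal(m$freqs[1, "A" == adductscan:::AA_ALPHABET], 3 / 22, tolerance = 1e-12)
  expect_equal(m$matrix[1, 1], log2((3 / 22) / 0.05), tolerance = 1e-9)
  expect_equal(log2((3 / 22) / 0.05), 1.4475, tolerance = 1e-4)
  # alpha -> 0 single sequence: consensus log2(1/0.05), zeros floored at -20
  m0 <- pssm_from_epitopes("AC", alpha = 0)
  expect_equal(m0$matrix[1, 1], log2(20), tolerance = 1e-9)
  expect_equal(log2(20), 4.3219, tolerance = 1e-4)
  expect_true(all(m0$matrix[1, -1] == -20))
  # identical column across n: frequency (n + alpha) / (n + 20 alpha)
  for (n in c(1, 3, 10)) {
    mm <- pssm_from_epitopes(rep("GG", n), alpha = 1)
    g <- which(adductscan:::AA_ALPHABET == "G")
    expect_equal(mm$freqs[1, g], (n + 1) / (n + 20), tolerance = 1e-12)
  }
  expect_error(pssm_from_epitopes(c("AA", "AAA")), "mixed")
})

test_that("implied per-position frequencies sum to one", {
  set.seed(4)
  seqs <- replicate(30, paste(sample(adductscan:::AA_ALPHABET, 9, replace = TRUE),
                              collapse = ""))
  m <- pssm_from_epitopes(seqs)
  implied <- rowSums(sweep(2^m$matrix, 2, m$background, "*"))
  expect_true(all(abs(implied - 1) < 1e-9))
})

test_that("peptide scores are additive position sums, maximal at the consensus", {
  spec <- plant_spec(seed = 5)
  pssm <- gen_pssm(spec)
  consensus <- attr(pssm, "consensus")
  set.seed(5)
  s <- paste(sample(adductscan:::AA_ALPHABET, 9, replace = TRUE), collapse = "")
  # split-and-sum: score equals the sum of per-position lookups
  chars <- strsplit(s, "")[[1]]
  manual <- sum(vapply(1:9, function(i) {
    pssm$matrix[i, match(chars[i], adductscan:::AA_ALPHABET)]
  }, numeric(1)))
  expect_equal(score_peptide(s, pssm), manual, tolerance = 1e-12)
  expect_lte(score_peptide(s, pssm), score_peptide(consensus, pssm))
  expect_error(score_peptide("AAAA", pssm), "length")
})

test_that("scores match exhaustive enumeration on a toy length-2 motif", {
  m <- pssm_from_epitopes(c("AC", "AC", "AD"), alpha = 1)
  all_peps <- as.vector(outer(adductscan:::AA_ALPHABET, adductscan:::AA_ALPHABET,
                              paste0))
  scores <- score_peptide(all_peps, m)
  brute <- vapply(all_peps, function(s) {
    ch <- strsplit(s, "")[[1]]
    m$matrix[1, match(ch[1], adductscan:::AA_ALPHABET)] +
      m$matrix[2, match(ch[2], adductscan:::AA_ALPHABET)]
  }, numeric(1))
  expect_equal(unname(scores), unname(brute), tolerance = 1e-12)
  expect_equal(all_peps[which.max(scores)], "AC")  # brute-force argmax
})

test_that("percentile rank counts background scores at or above the query", {
  bg <- c(1, 2, 3, 4)
  expect_equal(percentile_rank(10, bg), 0)
  expect_equal(percentile_rank(2.5, bg), 50)
  expect_equal(percentile_rank(1, bg), 100)        # all >= score
  grid <- seq(0, 5, by = 0.25)
  ranks <- percentile_rank(grid, bg)
  expect_true(all(diff(ranks) <= 0))               # non-increasing in score
  expect_error(percentile_rank(1, numeric(0)), "non-empty")
  expect_true(is_strong_binder(0.5))
  expect_false(is_strong_binder(0.51))
})

test_that("planted PSSMs are recovered from sampled sequences", {
  ok <- 0
  for (seed in 1:100) {
    spec <- plant_spec(seed = seed)
    pssm <- gen_pssm(spec)
    seqs <- sample_from_pssm(pssm, 1000, seed = seed)
    est <- pssm_from_epitopes(seqs, alpha = 0)
    if (max(abs(est$freqs - pssm$freqs)) < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("PSSM files round-trip through the square-matrix text format", {
  spec <- plant_spec(seed = 6)
  pssm <- gen_pssm(spec)
  f <- tempfile(fileext = ".tsv")
  write_pssm(pssm, f)
  back <- read_pssm(f)
  expect_equal(back$matrix, pssm$matrix, tolerance = 1e-6)
  s <- sample_from_pssm(pssm, 5, seed = 1)
  expect_equal(score_peptide(s, back), score_peptide(s, pssm), tolerance = 1e-4)
})

test_that("epitope TSV reader validates its contract", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sequence\tic50_nm\tallele", "LAGKNLTHI\t250\tH-2Db"), f)
  df <- read_epitope_tsv(f)
  expect_equal(classify_binder(df$ic50_nm), "binder")
  writeLines(c("sequence\tic50_nm\tallele", "LAGKNLTHI\t-3\tH-2Db"), f)
  expect_error(read_epitope_tsv(f), "positive")
})
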