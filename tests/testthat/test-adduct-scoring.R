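# Surrogate scoring backend, accommodation penalty, delta score, backends.

make_scoring_fixture <- function(seed = 1) {
  spec <- plant_spec(seed = seed)
  pssm <- gen_pssm(spec)
  list(spec = spec, pssm = pssm, allele = gen_allele(spec, pssm))
}

test_that("unmodified peptides score as pure negated PSSM terms", {
  fx <- make_scoring_fixture()
  p <- gen_lysine_peptides(fx$spec, n = 1)$sequence
  rep1 <- score_peptide_allele(p, fx$allele)
  expect_false(rep1$adducted)
  expect_equal(rep1$total, -score_peptide(p, fx$pssm), tolerance = 1e-12)
  expect_equal(sum(rep1$per_position), rep1$total, tolerance = 1e-9)
  # determinism: scoring twice is bit-identical
  expect_identical(rep1, score_peptide_allele(p, fx$allele))
})

test_that("per-position scores sum to the total on random inputs", {
  fx <- make_scoring_fixture(2)
  set.seed(2)
  for (i in 1:100) {
    chars <- sample(adductscan:::AA_ALPHABET, 9, replace = TRUE)
    kpos <- sample(1:9, 1)
    chars[kpos] <- "K"
    p <- parse_peptide(paste(chars, collapse = ""))
    if (i %% 2 == 0) p <- apply_adduct(p, kpos, "pyrrole")
    rep <- score_peptide_allele(p, fx$allele)
    total <- 0
    for (v in rep$per_position) total <- total + v   # independent accumulation
    expect_equal(total, rep$total, tolerance = 1e-9)
  }
})

test_that("accommodation penalty follows kappa * bulk * (1 - exposure)", {
  fx <- make_scoring_fixture()
  params <- surrogate_params(penalty_scale = 10)
  # fully exposed favorable position: free
  expect_equal(adduct_penalty(4, "pyrrole", fx$allele, params), 0)
  # fully buried limit
  buried <- fx$allele
  buried$exposure[["9"]][2] <- 0
  expect_equal(adduct_penalty(2, "pyrrole", buried, params), 10)
  # scales with bulk weight
  heavy <- adduct_species("heavy", c(C = 1), bulk_weight = 2)
  expect_equal(adduct_penalty(2, heavy, buried, params), 20)
})

test_that("the clash term counts receptor pseudo-atoms within the radius", {
  fx <- make_scoring_fixture()
  bb <- matrix(0, nrow = 9, ncol = 3)
  bb[, 1] <- seq(0, 32, by = 4)
  # three receptor atoms: two within 2.5 A of residue 1, one far away
  rc <- rbind(c(1, 0, 0, 1.8), c(0, 2, 0, 1.8), c(30, 30, 30, 1.8))
  mdl <- complex_model("LAGKNLTHI", backbone = bb, receptor_atoms = rc)
  params <- surrogate_params(penalty_scale = 0, clash_weight = 1,
                             clash_radius = 2.5, clash_term_enabled = TRUE)
  # brute-force distance check agrees
  d <- sqrt(colSums((t(rc[, 1:3]) - bb[1, ])^2))
  expect_equal(sum(d < 2.5), 2)
  expect_equal(adduct_penalty(1, "pyrrole", fx$allele, params, model = mdl), 2)
  expect_error(adduct_penalty(1, "pyrrole", fx$allele, params), "no backbone")
})

test_that("delta score equals the accommodation penalty under the surrogate", {
  fx <- make_scoring_fixture(3)
  params <- surrogate_params()
  peps <- gen_lysine_peptides(fx$spec, n = 50)
  for (i in seq_len(nrow(peps))) {
    mdl <- complex_model(peps$sequence[i])
    d <- delta_score(mdl, peps$k_position[i], "pyrrole", fx$allele, params)
    expect_equal(d, adduct_penalty(peps$k_position[i], "pyrrole", fx$allele, params),
                 tolerance = 1e-12)
    expect_gte(d, 0)
  }
  expect_error(delta_score(complex_model("LAGKNLTHI"), 5, "pyrrole", fx$allele),
               "not a lysine")
})

test_that("delta score is non-increasing in exposure", {
  fx <- make_scoring_fixture()
  grid <- seq(0, 1, by = 0.1)
  deltas <- vapply(grid, function(e) {
    a <- fx$allele
    a$exposure[["9"]][4] <- e
    delta_score(complex_model("LAGKNLTHI"), 4, "pyrrole", a)
  }, numeric(1))
  expect_true(all(diff(deltas) <= 1e-12))
  expect_equal(deltas[length(deltas)], 0)  # fully exposed: no score increase
})

test_that("restrictive alleles show larger mean delta scores than permissive ones", {
  spec <- plant_spec(seed = 9)
  pssm <- gen_pssm(spec)
  permissive <- gen_allele(spec, pssm, name = "permissive")
  restrictive <- permissive
  non_anchor <- setdiff(1:9, spec$anchors)
  restrictive$exposure[["9"]][non_anchor] <-
    permissive$exposure[["9"]][non_anchor] * 0.5
  peps <- gen_lysine_peptides(spec, n = 30)
  d_p <- vapply(seq_len(nrow(peps)), function(i) {
    delta_score(complex_model(peps$sequence[i]), peps$k_position[i], "pyrrole", permissive)
  }, numeric(1))
  d_r <- vapply(seq_len(nrow(peps)), function(i) {
    delta_score(complex_model(peps$sequence[i]), peps$k_position[i], "pyrrole", restrictive)
  }, numeric(1))
  expect_gt(mean(d_r), mean(d_p))
})

test_that("backend registry resolves by name and rejects duplicates", {
  adductscan:::reset_backends()
  on.exit(adductscan:::reset_backends())
  fx <- make_scoring_fixture()
  register_backend("noop", function(model, allele, params) {
    list(total = 0, per_position = rep(0, nchar(model$peptide$sequence)))
  })
  rep <- score_peptide_allele("LAGKNLTHI", fx$allele, backend = "noop")
  expect_equal(rep$total, 0)
  expect_equal(rep$backend, "noop")
  expect_error(register_backend("surrogate", identity), "already registered")
  err <- tryCatch(score_peptide_allele("LAGKNLTHI", fx$allele, backend = "bogus"),
                  error = conditionMessage)
  expect_match(err, "noop")
  expect_match(err, "surrogate")
})

test_that("ensemble interface settings are no-ops for the surrogate", {
  fx <- make_scoring_fixture()
  mdl <- complex_model("LAGKNLTHI")
  a <- score_complex(mdl, fx$allele, n_models = 1, top_k = 1)
  b <- score_complex(mdl, fx$allele, n_models = 250, top_k = 5)
  expect_identical(a, b)
})

test_that("unsupported peptide lengths are rejected", {
  fx <- make_scoring_fixture()
  expect_error(score_peptide_allele("LAGKNLTH", fx$allele), "length 8")
})
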