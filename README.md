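# adductscan

Isolevuglandins (IsoLGs) are reactive lipid-peroxidation products that
covalently modify the ε-amino group of protein lysines, forming a family of
pyrrole/lactam adducts. Modified self-peptides can be presented by class I
MHC and drive T cell activation — but only if the groove can physically
accommodate the bulky adduct and the peptide still binds its MHC allele.
`adductscan` is an R toolkit for the computational side of that problem:
given a proteome, tissue-expression data and an MHC allele model, it
identifies candidate self-peptides that (i) come from proteins
overexpressed in a target tissue, (ii) are predicted strong MHC-I binders,
and (iii) carry a lysine at a position where an IsoLG adduct is
energetically tolerated. It also computes the precursor m/z targets needed
to hunt those adducted peptides by parallel-reaction-monitoring mass
spectrometry.

It is aimed at immunologists and structural bioinformaticians designing
adducted-epitope screens (hypertension and other oxidative-stress
autoimmunity models), and at anyone who needs a transparent, fully testable
stand-in for heavyweight all-atom pipelines at the hypothesis-generation
stage.

## The model

**Threading and template selection.** A query 9-mer is threaded onto the
best same-length peptide–MHC template, chosen by the ungapped BLOSUM62
score S(q,t) = Σᵢ B62(qᵢ, tᵢ); backbone coordinates are copied unchanged
and residue identities swapped.

**Surrogate scoring.** The all-atom energy is replaced by a transparent
surrogate. For peptide p on allele a with position-specific scoring matrix
M and groove-exposure profile e ∈ [0,1]ᴸ:

    score(p) = Σᵢ [ −M(i, pᵢ) + 1{i adducted} · κ · w(s) · (1 − eᵢ) ]

with penalty scale κ (default 10), adduct bulk weight w(s), and an optional
clash-count term. Lower is more favorable. The change on in-silico
adduction at lysine position k,

    ΔScore(k) = score(p + adduct@k) − score(p) = κ · w(s) · (1 − eₖ),

is zero exactly when the position is fully solvent-exposed. A position is
called **favorable** when at least m peptides (default 2) show ΔScore ≤ τ
(default 0) there; group contrasts (binder vs nonbinder, allele vs allele)
use an exact Mann–Whitney rank-sum test (full enumeration for group sizes
≤ 8, tie-corrected normal approximation otherwise).

**Binder prediction.** PSSM log₂-odds scores are ranked against a seeded
background of 100,000 uniform-composition peptides; "strong binders" are
calls at percentile rank ≤ 0.5 (configurable). IC50-based truth uses the
inclusive 500 nM boundary.

**Masses.** Monoisotopic peptide masses with N-terminal acetylation
(+C2H2O) and IsoLG adduct deltas from a user-editable chemistry config
(shipped defaults are the IsoLG C20H32O4 + lysine condensation series);
precursor m/z = (M + z·m_H⁺)/z.

## Worked example

PRM targets for the kidney-derived SGLT2 peptide LAGKNLTHI, N-terminally
acetylated, pyrrole-adducted at its K4:

```sh
$ Rscript exec/adductscan mass-calc --peptide LAGKNLTHI --acetyl --adduct pyrrole@4 --charges 1,2
species z       mz
pyrrole 1       1308.792586
pyrrole 2       654.899931
```

These are the singly and doubly charged precursor m/z values you would put
on a PRM inclusion list for that adduct species.

A complete synthetic screen (generated fixtures with two planted
candidates):

```r
library(adductscan)
spec   <- plant_spec(seed = 42)            # favorable {4,6,7}, anchors {5,9}
pssm   <- gen_pssm(spec)
allele <- gen_allele(spec, pssm)
fx     <- gen_proteome(spec, pssm)
ct <- screen_candidates(fx$proteome, fx$expression, fx$orthologs,
                        allele, pssm, spec$favorable,
                        screen_config(seed = 42))
ct[ct$pass_all, c("protein", "start", "peptide", "lysine_positions",
                  "fold_change", "binder_rank")]
#>    protein start   peptide lysine_positions fold_change binder_rank
#> 16  MMP001    16 QIHKPCILC                4           8           0
#> 47  MMP002    16 QIHIPKILC                6           8           0
```

Both planted peptides — and nothing else — survive the three filters: an
8-fold kidney overexpression (above the strict >4-fold cutoff), percentile
rank 0 (stronger than the whole background sample), and a lysine at a
favorable position. Per-position adduction analysis on the same allele:

```r
peps <- gen_lysine_peptides(spec)
dt   <- build_delta_table(setNames(peps$sequence, peps$peptide_id), allele)
favorable_positions(per_position_delta(dt, tau = 0), m = 2)$positions
#> [1] 4 6 7
```

ΔScore is exactly 0 at the fully exposed positions 4, 6 and 7 and ≥ 6
surrogate units elsewhere, so the planted favorable set is recovered.

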