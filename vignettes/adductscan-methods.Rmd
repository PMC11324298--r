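---
title: "Methods: surrogate scoring and screening of IsoLG-adducted MHC-I peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate scoring and screening of IsoLG-adducted MHC-I peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adductscan)
```

## The problem

Isolevuglandin (IsoLG) adducts convert self-peptides into potential
neoepitopes, but presentation by class I MHC depends on two couplings: the
peptide must still satisfy the allele's binding motif, and the groove must
sterically tolerate a bulky lysine adduct at the modified position.
`adductscan` models both couplings with deliberately transparent
components — a PSSM for the motif, a groove-exposure profile for
accommodation — and chains them into the candidate-screening pipeline:
tissue-overexpression filter, ortholog mapping, 9-mer enumeration,
strong-binder filter, favorable-lysine filter, deduplication.

## The surrogate scorer and its assumptions

All-atom refinement pipelines score a peptide–MHC complex by ensemble
sampling (hundreds of models per complex, averaging the best few composite
scores). That machinery is deliberately replaced here by a deterministic
surrogate:

$$\mathrm{score}(p) = \sum_i \big[-M(i, p_i) +
  \mathbb{1}\{i\ \mathrm{adducted}\}\,\kappa\, w(s)\,(1 - e_i)\big]$$

* $M$ is the allele's PSSM in log2-odds bits; negating it makes lower
  scores more favorable, matching the convention that known binders score
  lower than nonbinders.
* $e_i \in [0,1]$ is the per-position groove exposure. The single
  structural assumption is that solvent accessibility is the mechanistic
  driver of adduct accommodation: positions whose side chains point at the
  T cell receptor can carry the adduct freely, buried ones cannot. Under
  this surrogate, $\Delta\mathrm{Score}$ after in-silico adduction at
  position $k$ reduces exactly to $\kappa\, w(s)\,(1-e_k)$, which is zero
  iff the position is fully exposed — so "favorable position" claims are
  closed-form auditable.
* The optional clash term adds `clash_weight` per receptor pseudo-atom
  within `clash_radius` of the position's backbone coordinate. It is off
  by default so that every worked example stays closed-form; geometry-free
  complexes (`complex_model(p)`) are valid whenever it is off.

Because the surrogate is deterministic, the ensemble-interface arguments
`n_models`/`top_k` are accepted but contractually ignored: they exist so an
external all-atom backend (registered via `register_backend()`, which must
return a single `total` plus a per-position decomposition) can be swapped
in without changing call sites. Whether an external backend's Δ should be
computed on best-model pairs or top-k averages is a question that simply
does not arise for the surrogate.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `penalty_scale` (κ) | 10 | surrogate score units | makes a fully buried adduct (~10 units) dominate typical per-position PSSM terms (±4–5 bits) |
| `bulk_weight` w(s) | 1 per species | unitless | the four IsoLG chemotypes are treated as equally bulky until calibrated data exist |
| `clash_radius` | 2.5 | Å | heavy-atom steric contact distance |
| binder threshold | 500 | nM IC50, inclusive | standard MHC-I binder cutoff |
| strong-binder rank | 0.5 | percentile | stand-in for the external predictor's unstated strong-binder default; configurable |
| background size | 100,000 | peptides | quantile noise at rank 0.5 is ~±0.02 percentile points; seeded and configurable |
| fold threshold | 4 | fold, strict `>` | tissue-enrichment convention; denominator is the max over non-target tissues (conservative), `mean` available |
| τ, m (favorable call) | 0, 2 | score units, count | the literal reading of "multiple peptides with no score increase"; both configurable |
| PSSM pseudocount α | 1 | counts | Laplace smoothing; log-odds floor −20 bits keeps α→0 finite while dominating any realistic score |

## Numerical and convention choices

* **Positions are 1-based everywhere** (immunology P1…P9 convention).
* **Rank-sum test.** U counts A-over-B pairs with ties as ½. Both group
  sizes ≤ 8: exact p over all $\binom{n_A+n_B}{n_A}$ labelings via the
  shift-algorithm DP on doubled midranks (ties exact). Larger groups:
  normal approximation with tie-corrected variance, no continuity
  correction. Two-sided p doubles the smaller inclusive tail, capped at 1
  (not mid-p) — the simplest exact convention, stated so results are
  reproducible to the last digit. Zero-variance (fully tied) data gives
  p = 1.
* **Template selection** scores ungapped, same-length only: same-length
  MHC-I peptides are modeled end-to-end in the groove, so gaps have no
  structural meaning here; mixed-length threading is out of scope. Ties
  break to the lexicographically smallest template id.
* **Minimal PDB dialect**: ATOM records only, peptide chain id
  configurable (default "C"), Å coordinates; records with altlocs or
  insertion codes invalidate that entry (skipped with a logged reason),
  never the whole library; an entry missing a unique Cα per residue is
  skipped likewise. Receptor pseudo-atoms are the non-peptide Cα centers
  at a constant 1.8 Å radius.
* **Overexpression edge cases**: a zero denominator with positive target
  expression counts as infinite fold (kept); proteins missing the target
  tissue row are excluded with a warning.
* **Dedup** keeps the first occurrence ordered by (protein id, offset).
* **Masses** are monoisotopic; the element table is a shipped constant
  file, overridable. N-terminal acetylation is a peptide-level flag (it is
  applied uniformly at synthesis to block N-terminal adduction), not a
  positional modification.

## Adduct chemistry

No calibrated elemental formulas are shipped for the four IsoLG-lysine
chemotypes; the defaults are documented placeholders from the IsoLG
(C20H32O4) + lysine condensation series — pyrrole = IsoLG − 2 H2O
(C20H28O2), lactam = pyrrole + O, anhydrolactam = lactam − H2O,
anhydropyrrole = pyrrole − H2O. All mass tests are therefore
oracle-derived (frozen values from an independent elemental-composition
implementation), never treated as literature ground truth. Replace
`inst/extdata/isolg_adducts.yaml` with instrument-calibrated compositions
for real PRM work. The registry ships all four species and leaves species
selection to the caller, since published accounts of which products
dominate vary.

## What the synthetic generators emulate — and what they do not

`plant_spec()` fixes the study conditions once: favorable positions
{4,6,7} at exposure 1.0, anchors {5,9} at 0.1, other positions drawn in
[0.15, 0.4]; PSSM softmax sharpness 6 (consensus frequency ≈ 0.95, an
anchor-like sharp motif); epitope sets of 200 binders + 200 nonbinders
with log10(IC50) linearly coupled to the PSSM score (calibrated so binders
sit at ~32 nM and nonbinders at ~32 µM in expectation, noise σ = 0.5 log10
units); proteomes of 12 proteins with planted candidates at 8-fold kidney
overexpression against background folds < 3. A single master seed drives
named RNG sub-streams, so adding a generator never perturbs existing
fixtures.

Planted proteins are constructed so the truth list is provably the unique
fully-passing set: flanks are lysine-free, and a deterministic repair pass
mutates flank residues (to the column-minimum residue) in any off-frame
window that would carry the planted K at a favorable frame position with a
background-beating score. This is what makes "zero false positives over
100 seeds" a designed property rather than a statistical accident.

What the generators do **not** emulate: real tissue-expression covariance,
proteome composition bias and repeat structure, immunopeptidome length
distributions, correlated measurement error in IC50s, and real groove
exposure profiles (which vary smoothly, not as planted plateaus). Passing
the planted-recovery tests therefore demonstrates that the pipeline's
logic is correct and deterministic — not that its defaults are calibrated
for any particular organism's data.

## Problem sizes used by the tests and acceptance script

Recovery and separation properties are evaluated over 100 seeds each
(template-selection oracle equivalence over 50 libraries of 20 templates;
mass identities over 1,000 random peptides; screens at the full default
background of 100,000 peptides). These sizes make each statistical
property's success criterion (≥ 95/100 seeds where sampling noise exists,
100/100 where the property is deterministic) meaningful while keeping a
full run in well under a minute per property on one core.

## Known limitations

* The surrogate cannot reproduce absolute all-atom energies, and its
  ΔScore is linear in exposure by construction; it ranks positions, it
  does not predict binding free energies.
* Anchor definitions for 8-mers on the 9-mer-preferring allele are
  configuration defaults, not structural claims.
* The external-backend adapter is a contract plus registry only; no
  all-atom backend is bundled or tested beyond the registry mechanics.
* The HLA panel rule applies both published criteria (frequency > 5% and
  top-10 per population) because sources state them inconsistently; both
  knobs are exposed and neither is privileged.
* Fragment-ion ladders, retention time and spectral matching are out of
  scope; only precursor m/z targets are computed.
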