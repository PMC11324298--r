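# IsoLG lysine-adduct chemotypes.
#
# Elemental deltas are documented placeholders from the IsoLG (C20H32O4) +
# lysine condensation series:
#   pyrrole        = IsoLG - 2 H2O        -> C20 H28 O2
#   lactam         = pyrrole + O          -> C20 H28 O3
#   anhydrolactam  = lactam - H2O         -> C20 H26 O2
#   anhydropyrrole = pyrrole - H2O        -> C20 H26 O
# Replace with instrument-calibrated compositions where available.
# bulk_weight is the unitless accommodation-penalty weight used by the
# surrogate scorer (all chemotypes treated as equally bulky by default).
species:
  pyrrole:
    delta: {C: 20, H: 28, O: 2}
    bulk_weight: 1.0
  lactam:
    delta: {C: 20, H: 28, O: 3}
    bulk_weight: 1.0
  anhydrolactam:
    delta: {C: 20, H: 26, O: 2}
    bulk_weight: 1.0
  anhydropyrrole:
    delta: {C: 20, H: 26, O: 1}
    bulk_weight: 1.0
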