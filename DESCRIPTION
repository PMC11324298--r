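Package: adductscan
Title: Screening Self-Peptides for MHC Class I Presentation of Isolevuglandin Lysine Adducts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying self-peptides that can carry an
    isolevuglandin (IsoLG) lysine adduct and still be presented by class I
    MHC. Provides template-based peptide threading onto solved peptide-MHC
    structures with BLOSUM62 template selection, a transparent
    exposure-driven surrogate scorer for in-silico adduction and the
    per-position delta-score statistic, position-specific scoring matrix
    (PSSM) binder prediction with percentile-rank strong-binder calls, the
    multi-filter candidate-screening pipeline (tissue overexpression,
    ortholog mapping, k-mer enumeration, binder and favorable-lysine
    filters), HLA allele-frequency panel selection, and monoisotopic
    precursor m/z computation for parallel-reaction-monitoring target lists
    of adducted peptides. A seeded synthetic-data module generates every
    pipeline input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d
Config/testthat/edition: 3
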