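Package: orientddg
Title: Orientational Backbone Statistical Potential for Protein Stability
    Change Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives a residue-level orientational pair potential from
    protein backbone geometry by Boltzmann inversion and applies it,
    through fitted amino-acid-group weights, to predict changes in protein
    unfolding free energy upon point mutation. Includes curation of
    experimental stability datasets (condition windows, replicate merging,
    structure-quality and ligand-proximity screens, alanine debiasing,
    homology clustering), homology-aware cross-validated weight fitting by
    derivative-free minimisation of the mean absolute error, a full
    evaluation suite (regression, binary and three-state classification,
    ROC/PRC, anti-symmetry diagnostics), and deterministic synthetic
    fixtures (ideal helices, ground-truth mutation tables) so the whole
    pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
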