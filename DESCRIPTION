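Package: phipsi
Title: Two-Level Support Vector Regression Prediction of Protein
    Backbone Torsion Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Real-value prediction of protein backbone torsion angles
    (phi, psi) from sequence-derived profiles using a two-level
    epsilon-support-vector-regression cascade with an RBF kernel.  The
    package reads the standard per-residue profile dialects (PSI-BLAST
    ASCII position-specific scoring matrices, PSIPRED ss2 secondary
    structure, two-state solvent accessibility, disorder probabilities),
    encodes residues with sliding-window schemes, computes backbone
    dihedrals from PDB coordinates, evaluates predictions with Pearson
    correlation, mean absolute error and root-mean-square error on raw
    and normalized scales with circular or linear angle differences,
    provides the amino-acid-specific random-angle null model, and ships
    a synthetic-profile generator so the whole pipeline runs without the
    external profile predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
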