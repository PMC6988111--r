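Package: proteovary
Title: Proteotype Variation Analysis via Protein Complex Co-Abundance and
    Stoichiometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantifying inter-individual variation of the
    proteome ("proteotype") through known functional modules. Quantifies a
    cohort's power to recover protein complexes, pathways and other modules
    from pairwise co-abundance (ROC/AUC with subsampled Mann-Whitney tests),
    aggregates within-complex co-abundance ranks across datasets into a
    stable/variable complex landscape with permutation and decoy nulls,
    decomposes complexes into stable and variable subunit components via
    trimmed-mean complex normalization and variance z-scores, tests sex- and
    diet-dependence of complex abundance (Cohen's d) and stoichiometry
    (empirical-Bayes moderated contrasts with Fisher combination), and
    estimates covariate effect sizes as cross-validated ridge-regression
    variance explained with permutation-based empirical FDR. Includes a
    synthetic multi-dataset cohort generator with planted modular covariance,
    variable subunits and covariate effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'covariates.R'
    'stoichiometry.R'
    'recovery.R'
    'landscape.R'
    'effect_size.R'
    'pipeline.R'
    'preprocess.R'
    'synthetic.R'
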