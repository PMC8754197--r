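Package: savpred
Title: Missense Variant Pathogenicity Prediction from Conservation,
    Structure and Dynamics Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A feature pipeline and gradient-boosted classifier for
    predicting the pathogenicity of single amino acid variants (SAVs).
    Computes per-position variation numbers (a phylogenetic conservation
    score based on Fitch small-parsimony counts over a neighbor-joining
    ortholog tree), anisotropic network model dynamics features (mean
    squared displacement, mechanical stiffness, perturbation-response
    effectiveness and sensitivity), and Shrake-Rupley solvent accessible
    surface area; ingests tool-derived features such as folding free
    energy changes and PSIC profile scores; assembles a 15-feature matrix
    per variant with ClinVar-style labels; and evaluates an XGBoost
    classifier by stratified ten-fold cross-validation with accuracy,
    sensitivity, specificity, F1, Matthews correlation, ROC/PR curves,
    leave-one-feature-out ablation and deep mutational scanning
    benchmarks. A synthetic-data module generates ortholog families,
    idealized structures, feature datasets and DMS tables so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    MASS,
    phangorn,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
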