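Package: decoyscreen
Title: Decoy Cohort Construction, Bias Auditing and Early-Recognition
    Evaluation for Ligand-Based Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for building and auditing negative (decoy) cohorts for
    molecular screening classifiers. Standardizes structures and removes
    positive/decoy identity overlap via InChIKeys, applies a strict
    rule-engine (promoiety, warhead and structural-alert SMARTS plus
    drug-likeness property windows) to derive high-confidence negatives,
    computes 2048-bit hashed binary substructure fingerprints, freezes a
    source-balanced 1:6 train/test split, and applies training-only decoy
    guardrails (Tanimoto similarity bounds, source-predictability pruning,
    cluster source-entropy filtering). A domain-bias audit quantifies how
    well a feature subset predicts decoy origin and gates subsets at
    near-chance; cross-decoy transfer validation and an equal-weight
    late-fusion ensemble over feature views complete the modelling stack.
    Evaluation covers enrichment factors, BEDROC, ROC AUC, average
    precision and label-randomization chance checks, with a synthetic
    fingerprint generator for fully self-contained pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    class,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
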