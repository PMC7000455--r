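Package: drpsc
Title: Signature-Reversal Drug Repositioning with Pharmacogene-Weighted
    Perturbation Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores drugs for repositioning by how strongly their induced
    gene or protein perturbation signatures invert a disease signature,
    weighting the evidence by perturbation of pharmacogenes (drug targets,
    enzymes, transporters and carriers). Builds drug-induced log2
    fold-change signature databases from treated-versus-control expression
    profiles, derives disease signatures by differential-expression
    filtering with Benjamini-Hochberg control, computes the Drug
    Repositioning Perturbation Score (DRPS) maximised over experimental
    conditions, classifies drugs into high/intermediate/low tertile
    classes, validates rankings by per-class ROC/AUC against a
    prescribed-drug gold standard, and selects multi-omics candidates.
    Includes a synthetic-data generator with planted reversal structure so
    the whole pipeline is testable without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
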