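Package: mirisk
Title: Serum MicroRNA Risk Scores for Colorectal Cancer Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for deriving and benchmarking circulating
    microRNA risk scores for colorectal cancer risk prediction from serum
    qPCR panels. Implements qPCR quality control (spike-in monitoring,
    hemolysis flagging via the miR-23a/miR-451a delta-Cq rule, assay
    validity and detectability filters), NormFinder reference-miRNA
    selection and delta-Cq normalization, NGS-phase candidate discovery
    (TMM normalization, a simplified negative-binomial exact test, FDR and
    fold-change filters), logistic-regression miRNA panel scores, a
    point-based environmental risk score with chained-equation imputation,
    a weighted-allele-sum polygenic risk score, quintile-stratified odds
    ratios, and optimism-corrected predictive performance (AUC, Brier)
    via the .632+ bootstrap. A synthetic-cohort generator with recorded
    ground truth makes every stage testable without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
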