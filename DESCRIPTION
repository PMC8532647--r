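Package: oxiswitch
Title: Post-Acquisition LC-MS Metabolomics Pipeline with QC-SVR Drift
    Correction, Feature Filtering and Pathway Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for post-processing aligned untargeted LC-MS peak tables
    from clinical metabolomics batches: per-feature intra-batch signal drift
    correction by support vector regression on pooled quality-control (QC)
    injections, blank/QC-RSD/drug-ion feature filtering, derivation of
    cerebral fractional tissue oxygen extraction (FTOE) from near-infrared
    spectroscopy oximetry, feature-FTOE Pearson correlation screening,
    principal component analysis and Ward hierarchical clustering,
    mummichog-style m/z pathway enrichment with a permutation-gamma null,
    and rank-based statistics for targeted lipid-peroxidation biomarker
    panels.  Includes a synthetic-data generator that emulates a
    single-batch QC design (conditioning injections, periodic QCs, blanks,
    injection-order drift) with known planted structure so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
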