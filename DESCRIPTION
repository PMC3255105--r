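Package: selditree
Title: SELDI-TOF Serum Proteomic Profiling and Oblique Classification
    Trees for Lymph-Node Staging
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable re-implementation of a serum SELDI-TOF-MS
    biomarker pipeline for discriminating node-positive from
    node-negative colorectal-cancer patients: spectrum preprocessing
    (morphological baseline subtraction, mass windowing, total-ion-current
    normalization), Biomarker-Wizard-style two-pass peak detection and
    cross-spectrum peak clustering into a sample-by-peak intensity
    matrix, univariate screening (Student t, chi-square), an oblique
    (linear-combination-split) classification tree with Gini impurity,
    cost-complexity pruning and cross-validation, and confusion-matrix
    performance reporting.  Because the original raw spectra were never
    deposited, the package ships a synthetic-spectrum generator
    parameterized from the published class-conditional peak panel, so
    the whole pipeline is testable end to end without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
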