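Package: sbrtfx
Title: Radiobiological Fraction-Scheme Comparison for Lung SBRT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiobiological outcome modeling of stereotactic body
    radiotherapy (SBRT) fraction schemes in peripheral lung tumors. Converts
    structure dose-volume histograms (DVHs) to EQD2 or BED under the
    linear-quadratic model, computes tumor control probability (TCP) with five
    published models (Martel, Fenwick, Webb-Nahum, EUD-based, Nitin), estimates
    lung normal tissue complication probability (NTCP) with the
    Lyman-Kutcher-Burman and Fenwick mean-lung-dose models and chest-wall
    toxicity with a modified equivalent uniform dose (mEUD), and compares
    arbitrary fraction schemes on a cohort with paired Wilcoxon tests,
    lung/chest-wall risk stratification and an optimal-scheme decision rule.
    Includes a synthetic-cohort generator that emulates SBRT planning DVHs so
    the full pipeline is reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
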