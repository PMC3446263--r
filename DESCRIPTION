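Package: metaboflow
Title: Post-Deconvolution Processing and Differential Correlation
    Analysis for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational stages that follow peak
    deconvolution in untargeted liquid chromatography-mass spectrometry
    (LC-MS) metabolomics: quality-control robust loess signal correction
    (QC-RLSC) of injection-order drift, QC-based quality-assurance
    filtering, principal component analysis with total-signal outlier
    flagging, Mann-Whitney differential-feature testing with a two-study
    replication filter, bootstrapped Spearman differential-correlation
    ("reversal") analysis for detecting treatment-restored metabolite
    correlations, ppm-tolerance putative annotation with isotope-spacing
    charge-state assignment, and a synthetic-data generator emulating a
    two-study, four-group pooled-QC study design for method validation.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
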