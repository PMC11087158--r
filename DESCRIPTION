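Package: oardose
Title: Dosimetric Evaluation of Autosegmented Organs-at-Risk
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the dosimetric impact of organ-at-risk
    autosegmentation in brain radiotherapy. Computes dose-volume histogram
    statistics (D1%, D5%, D50%, maximum dose) and gold-vs-auto dose deltas on
    shared voxel grids, geometric agreement metrics (Dice similarity
    coefficient, sensitivity, mean distance-to-agreement), headroom-based
    clinical-significance thresholds per organ tier and protocol, paired model
    comparisons with Bonferroni control, and Pearson geometric-dosimetric
    correlations. Includes a synthetic head-phantom cohort generator (VMAT-like
    logistic dose falloff, parameterized autosegmentation error modes), minimal
    NIfTI-1 grid I/O, a JSON cohort manifest, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
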