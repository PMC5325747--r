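Package: tndecide
Title: Decision Analysis of Microvascular Decompression Versus Stereotactic
    Radiosurgery for Trigeminal Neuralgia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic comparison of microvascular decompression (MVD)
    and stereotactic radiosurgery (SRS) for medically refractory trigeminal
    neuralgia.  Provides a generic chance-node decision tree with rollback and
    exhaustive path enumeration, a quality-adjusted life year (QALY) model of
    pain outcomes on the Barrow Neurological Institute (BNI) scale with
    complications, recurrence and capped re-treatment, DerSimonian-Laird
    random-effects pooling and meta-regression of study-level proportions, a
    two-dimensional (parameter by patient) Monte Carlo probabilistic
    sensitivity analysis with beta-distributed inputs, and a synthetic
    study-corpus generator for end-to-end testing against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    metafor
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
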