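Package: cncrasch
Title: Rasch Measurement and Responsiveness Indices for the Coma/Near-Coma Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts ordinal Coma/Near-Coma (CNC) scale assessments of
    patients with disorders of consciousness to interval-scale logit person
    measures with the Andrich rating scale (polytomous Rasch) model, fitted
    by joint maximum likelihood with PROX initialisation and alternating
    Newton-Raphson steps.  From paired baseline/follow-up person measures it
    computes the standard panel of clinical responsiveness indices: pooled
    standard deviation, Wright's person separation reliability, standard
    error of measurement, minimal detectable change at 95% confidence
    (MDC95), distribution-based minimal clinically important differences at
    0.20/0.33/0.50 SD, effect size and standardized response mean, and
    classifies individual change as beyond or within measurement error.
    Includes a rating-scale-model cohort simulator for validation, raw
    score-to-measure conversion tables, and published CNC reference tables
    as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
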