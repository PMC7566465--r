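Package: msweib
Title: Parametric Weibull Markov Multistate Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits transition-specific Weibull proportional-hazards models to
    multistate event-history data with delayed entry (clock-forward Markov
    time scale), predicts transition and state-occupation probabilities by
    Kolmogorov-forward-equation integration and by Markov path simulation,
    and compares covariate models by AIC. Includes nonparametric
    Nelson-Aalen and Aalen-Johansen estimators for model-free validation,
    and a synthetic cohort generator calibrated to the published clinical
    course of prefibrotic primary myelofibrosis (pre-PMF, overt PMF, acute
    myeloid leukemia, death).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    flexsurv,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
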