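Package: jmsched
Title: Risk-Profile Based Adaptive Scheduling of Biomarker Monitoring Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint models for multivariate longitudinal biomarkers and
    competing time-to-event outcomes, Monte-Carlo dynamic predictions of
    conditional cumulative incidence, and risk-profile based optimization of
    the interval until the next monitoring visit. Includes a cohort simulator
    emulating quarterly biomarker follow-up of stable chronic heart failure
    patients (log NT-proBNP and log troponin T, heart-failure hospitalization
    and all-cause mortality as competing events), Bayesian estimation of the
    joint model (adaptive Metropolis and a fast maximum a posteriori plus
    Laplace mode), fixed and adaptive visit-scheduling strategies with an
    interruption rule, and a simulation-study driver comparing strategies on
    measurement burden, interruption accuracy, and interruption-timing error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    ggplot2
Config/testthat/edition: 3
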