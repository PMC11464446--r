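Package: psm3cea
Title: Three-State Partitioned-Survival Cost-Effectiveness Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort cost-effectiveness analysis built on a three-state
    (progression-free, progressed, dead) partitioned-survival model with
    parametric extrapolation of digitized Kaplan-Meier curves.  Provides six
    parametric survival families with maximum-likelihood and least-squares
    fitting and AIC/BIC model selection, a 21-day-cycle cohort engine with
    discounting and an optional background-mortality floor, full costing of
    drug acquisition (weight-, body-surface-area- and Calvert-based dosing
    with whole-vial pricing), adverse events, supportive and terminal care,
    one-way and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, joint price-threshold search, hazard-ratio-based
    subgroup analysis, and scenario machinery.  Ships a fully specified
    configuration reproducing a published evaluation of enfortumab vedotin
    plus pembrolizumab versus platinum-based chemotherapy as first-line
    treatment for advanced urothelial carcinoma from a Chinese healthcare
    perspective, together with synthetic-data generators (simulated
    individual patient data, Kaplan-Meier estimation, digitization
    emulation) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    optparse
Config/testthat/edition: 3
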