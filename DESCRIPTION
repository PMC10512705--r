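Package: tacelen
Title: Markov Cohort Cost-Effectiveness Model of TACE Plus Lenvatinib in
    Advanced Hepatocellular Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-state (progression-free, recurrence-free after
    down-staging hepatectomy, progressed disease, death) Markov cohort model
    comparing transarterial chemoembolization combined with lenvatinib
    against lenvatinib alone as first-line therapy for advanced
    hepatocellular carcinoma, from the Chinese healthcare-system
    perspective.  Includes log-logistic (and other parametric) survival
    extrapolation with AIC/BIC model selection, hazard-ratio adjustment,
    pseudo individual-patient-data simulation and Kaplan-Meier curve
    reconstruction, discounted cost/QALY accounting, one-way (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and subgroup and scenario drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
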