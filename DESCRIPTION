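Package: ceapsm
Title: Partitioned-Survival Cost-Effectiveness Model for First-Line
    Immunochemotherapy in Advanced Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead)
    partitioned-survival cohort model for evaluating the cost-effectiveness
    of tislelizumab plus chemotherapy against chemotherapy alone as
    first-line treatment of advanced gastric or gastroesophageal junction
    adenocarcinoma, from the China and United States payer perspectives.
    Includes parametric survival fitting over eight distribution families
    with AIC/BIC model selection, reconstruction of pseudo
    individual-patient data from digitized Kaplan-Meier curves and
    number-at-risk tables, incremental cost-effectiveness indices
    (ICER, INHB, INMB), one-way and probabilistic sensitivity analysis
    with acceptability curves, drug price-threshold simulation, scenario
    analysis over subsequent treatments, and a synthetic two-arm trial
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    graphics,
    grDevices,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
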