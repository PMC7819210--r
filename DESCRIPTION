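Package: protonCEA
Title: Individualized Cost-Effectiveness Analysis of Proton Versus Photon
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic modelling of the incremental
    cost-effectiveness of intensity-modulated proton therapy (IMPT)
    relative to photon IMRT for oropharyngeal cancer, at the level of the
    individual patient. Per-patient normal tissue complication
    probabilities (NTCP) for five toxicities feed a discounted
    quality-adjusted life year (QALY) model and a complication-management
    cost model; Monte Carlo probabilistic sensitivity analysis propagates
    parameter uncertainty (beta-distributed utilities, truncated-normal
    management proportions, log-scale hazard ratio for smoking) into
    per-sample incremental cost-effectiveness ratios (ICER) with dominance
    classification, willingness-to-pay threshold summaries,
    cost-effectiveness acceptability curves, subgroup reports and one-way
    scenario analyses. A synthetic cohort generator emulates the cohort
    structure the analysis assumes so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
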