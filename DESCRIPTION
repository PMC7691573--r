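Package: medsurg
Title: Causal Mediation Analysis for Surgical Trials with Binary
    Co-Intervention Mediators and Clustered Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates natural direct, natural indirect, total and
    controlled direct effects of a randomised (surgical) intervention on a
    binary outcome when a binary co-intervention acts as a mediator and
    patient outcomes are clustered within surgeons.  Mediator and outcome
    are modelled by mixed-effects logistic regressions with a surgeon
    random intercept; effects on the probability-difference scale are
    obtained by Monte Carlo simulation of potential mediators and
    outcomes, with nonparametric bootstrap confidence intervals and a
    sensitivity analysis for unmeasured mediator-outcome confounding
    parameterised by the confounder's log odds ratio on outcome and its
    mean contrast across mediator levels.  Includes a synthetic trial
    generator for design studies and method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    lme4,
    stats,
    graphics,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
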