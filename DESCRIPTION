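Package: tacropop
Title: Population Pharmacokinetics of Tacrolimus After Adult Liver
    Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of tacrolimus
    trough concentrations collected by routine therapeutic drug
    monitoring early after adult liver transplantation.  Implements two
    modelling strategies: an empirical Michaelis-Menten dose-trough
    model with a time-varying Michaelis constant, and a theory-based
    one-compartment plasma model with saturable erythrocyte binding
    (hematocrit-dependent whole-blood/plasma partition).  Provides
    first-order conditional estimation with interaction (FOCE-I) for
    nonlinear mixed-effects fitting, stepwise covariate selection,
    model diagnostics (prediction-error metrics, nonparametric
    bootstrap, prediction- and variability-corrected visual predictive
    checks, normalized prediction distribution errors), Monte Carlo
    starting-dose tables stratified by genotype, antifungal co-therapy,
    hematocrit and bilirubin, and a synthetic cohort generator that
    emulates the dose-titration feedback of therapeutic drug
    monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
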