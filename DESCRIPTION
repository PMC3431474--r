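Package: tktdsurv
Title: Toxicokinetic-Toxicodynamic Survival Models for Pulsed Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toxicokinetic-toxicodynamic (TKTD) survival analysis for
    aquatic organisms under pulsed and constant contaminant exposure, in
    the GUTS (general unified threshold model of survival) family. Fits
    one-compartment toxicokinetics, simulates four survival model variants
    (full/reduced toxicokinetics crossed with stochastic-death and
    individual-tolerance death mechanisms) with piecewise-analytic
    integration of step exposure profiles, calibrates them by two-step
    maximum likelihood on interval-censored survivor counts, computes
    profile-likelihood confidence intervals, log-logistic LC50
    dose-response fits, organism recovery times and model comparison
    tables, and generates synthetic study data emulating pulsed and acute
    toxicity designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
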