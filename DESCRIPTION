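Package: irrbias
Title: Odds Ratio versus Incidence Rate Ratio under Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation machinery for quantifying how a competing event
    (death) makes the odds ratio from a classical case-control study diverge
    from the incidence rate ratio targeted by incidence density sampling, in
    the setting of single-marker genetic association studies. Provides
    cause-specific Gompertz hazards parameterized by density mode and shape,
    calibration of the disease hazard to a target lifetime risk, a
    competing-risks cohort simulator with Hardy-Weinberg genotypes, classical
    and 1:m time-matched control sampling designs, logistic and conditional
    logistic association estimators, a deterministic large-sample odds-ratio
    oracle, and a replicate grid driver with sign-based empirical p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
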