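Package: hedgelife
Title: Actuarial Life Tables and Mortality Analysis for European Hedgehog Age-at-Death Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for demographic analysis of wildlife age-at-death records,
    developed around citizen-science collections of European hedgehogs
    (Erinaceus europaeus) aged by counting periosteal growth lines. Builds
    empirical single-year cohort life tables (lx, ndx, nqx, nLx, Tx, ex, nmx)
    from age-at-death counts, derives survivorship and hazard trajectories
    with a Type I/II/III classification test, computes stratified mean
    age-at-death with normal-theory confidence intervals, monthly death
    distributions and cause/habitat cross-tabulations, fits quasi-Poisson
    generalized linear models by iteratively reweighted least squares for
    inbreeding and cause-of-death effects, classifies death sites as urban or
    rural from an integer-coded land-cover grid, and simulates synthetic
    cohorts with configurable sex-specific hazard schedules for validation by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
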