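Package: cstdppk
Title: Population-Pharmacokinetic Interpretation of POP Breast-Milk Time Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting cross-sectional time trends (CSTD) of
    persistent organic pollutants (POPs) in human breast milk. Provides a
    dynamic, multigenerational population-pharmacokinetic (PPK) simulator of
    lipid-normalized body burdens (age-varying body and lipid weight, in
    utero and breastfeeding transfer), a static one-compartment PPK model
    with a closed-form solution, log-linear trend fitting that converts
    slopes into doubling and halving times, an inverse estimator of the
    intrinsic elimination half-life from concentration and intake time
    series, and a rule-based engine that flags when fitted halving times may
    be read as intake trends or elimination half-lives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
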