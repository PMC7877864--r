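Package: cdqsp
Title: Quantitative Systems Pharmacology Simulation of Biomarker Response in Crohn's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic ordinary-differential-equation model of the Crohn's
    disease immune cytokine network coupled to two-compartment antibody
    pharmacokinetics and quasi-equilibrium drug-cytokine binding. Generates
    virtual patient populations by sampling mechanistic parameters, selects
    trial-matched subpopulations against reported baseline C-reactive protein
    and fecal calprotectin statistics, simulates induction dosing arms for
    anti-TNFa, anti-IL-12p40, anti-IL-23 and anti-IL-6 antibodies, stratifies
    biomarker responders under percent-change and absolute cutoff rules, and
    predicts combination-therapy response. Includes calibration of nominal
    model parameters to printed clinical dose-response data and fully
    synthetic trial-report fixtures so every pipeline stage runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
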