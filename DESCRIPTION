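Package: senodem
Title: Senescent-Cell Dynamics and the Demography of Cancer and Ageing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic model of damaged- and senescent-cell accumulation
    in a tissue, coupled to organism-level competing-risks demography.
    Damaged cells either undergo apoptosis (triggering compensatory
    proliferation that re-seeds damage) or enter permanent cell-cycle arrest
    (cellular senescence); the tissue proportions of damaged and senescent
    cells drive, respectively, cancer mortality and other ageing-related
    mortality. The package searches for the senescence-entry probability
    that maximizes lifetime reproductive success over a Latin-hypercube
    sample of cellular and life-history parameters, classifies late-life
    deceleration and decline of age-specific cancer incidence, computes
    lifetime cancer prevalence in wild and captive settings, and runs
    in-silico senolysis experiments, together with the regression and
    sequential-ANOVA layer used to summarize the parameter sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lhs,
    stats,
    graphics,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
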