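Package: twinconfound
Title: Twin and Polygenic-Score Analysis of Media Use and Mental Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genetically informed analysis of the association between online
    media use and mental health in young adults: univariate and bivariate ACE
    twin models (Falconer approximations and constrained maximum-likelihood
    fits with profile-likelihood intervals), polygenic-score correlation and
    multiple-regression analysis, a heritability-scenario genetic-confounding
    sensitivity analysis, and a synthetic twin-cohort generator with known
    ground truth against which every downstream stage is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
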