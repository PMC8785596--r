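Package: sqhpf
Title: Development and Scoring of a Highly Processed Food Screening Questionnaire
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to develop, validate and score a short screening
    questionnaire for highly processed food (HPF) consumption from a
    semi-quantitative food-frequency questionnaire (FFQ). Computes
    per-system HPF consumption shares under the NOVA, IARC, IFIC and UNC
    food-processing classifications, constructs a tertile-agreement
    outcome, performs covariate-adjusted binomial logistic item selection
    with Bonferroni correction, derives Youden-index cutpoints mapped onto
    the nine FFQ answer categories, runs psychometric validation
    (principal-axis factor analysis, Kaiser-Meyer-Olkin sampling adequacy,
    Bartlett's sphericity, Cronbach's alpha, weighted Cohen's kappa), and
    calibrates the resulting score against FFQ-derived HPF percentages.
    Includes a seeded synthetic-cohort generator so the whole development
    pipeline can be exercised end to end without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
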