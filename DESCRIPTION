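Package: landshift
Title: Species Distribution Modelling of Diet-Driven Land-Use Change Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step species distribution modelling pipeline for assessing
    biodiversity impacts of converting grazing land to horticulture and natural
    land covers on a gridded landscape. Fits per-species climatic envelopes with
    a three-learner ensemble (rectilinear envelope, logistic regression, random
    forest) screened by cross-validated AUC and combined by two-thirds consensus,
    then models occurrence within climatically suitable area as a Bayesian
    no-intercept logistic function of 24 land-cover proportions with elicited
    normal priors. Provides scenario arithmetic converting production changes to
    land-exchange fractions, Local/Best/Worst spatial allocation strategies,
    and impact statistics (expected habitable area with linearised uncertainty,
    gain/loss probabilities at a relative change level, species-count
    distributions with credibility intervals). Includes a seeded virtual-species
    simulator so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
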