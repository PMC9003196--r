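Package: nutriplanr
Title: Food-Plan Construction, Intake Logging and Interaction-Cost Modelling for Precision Nutrition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational core of a nutritionist/user food-plan
    workflow: resting and total energy expenditure estimation (Harris-Benedict,
    Mifflin-St Jeor, Katch-McArdle, Cunningham; physical activity level by
    lifestyle category or 24-hour time allocation), macronutrient energy splits
    with Atwater gram conversion, food-plan totals and validation against
    targets, nutrient-equivalent food substitution, temperature-driven
    hydration goals, intake/water/activity logging with device-export
    ingestion, exponential-decay food-preference learning, and a
    keystroke-level-model (KLM) estimator of user interaction time. Includes
    seeded synthetic fixture generators so every analysis is reproducible
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
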