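Package: runfuel
Title: Fuel Metabolism, Glycogen Depletion, and Pacing Predictions for Endurance Runners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body metabolic model of endurance running. Fits the
    intensity dependence of carbohydrate versus fat oxidation to anchor
    measurements, converts among running speed, metabolic power, oxygen
    uptake, and aerobic capacity (including heart-rate-based VO2max
    estimation), accounts for physiologic glycogen reservoirs (liver,
    leg muscle, plasma), and predicts the carbohydrate budget of a race,
    the distance at which glycogen reserves are exhausted ('hitting the
    wall'), the minimum midrace carbohydrate intake needed to avoid it,
    and first-order error bounds on every derived quantity. Includes a
    synthetic-cohort generator, figure-style summary tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
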