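Package: nutriscox
Title: 2023 Nutri-Score Nutrient Profiling, Dietary Indices and
    Mortality Survival Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the 2023 updated Nutri-Score nutrient profiling
    model as a table-driven food and beverage scoring engine (unfavourable
    and favourable component points, conditional protein rules, letter
    classes), converts food frequency questionnaire (FFQ) responses into
    daily intakes, computes the energy-weighted Nutri-Score dietary index
    with cumulative averaging over repeated FFQs, and fits the
    accompanying epidemiological survival models: time-dependent Cox
    regression across dietary-index quintiles with cluster-robust
    variance, median-based trend tests, per-SD continuous models,
    interaction and subgroup analyses, early-death sensitivity analyses
    and Fine-Gray competing-risks models. A synthetic-cohort generator
    with known diet-quality structure and cause-specific mortality makes
    every stage testable without access to restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
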