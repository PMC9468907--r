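Package: grasslawns
Title: Trait-Based Classification and Environmental Analysis of Frequently
    Grazed Grass Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing quadrat surveys of frequently grazed
    grasslands. Computes four species-level grass trait indices (culm
    orientation, lateral spread, tuftedness, grazer use) from field records,
    classifies species into growth forms by hierarchical clustering on
    principal components with v-test cluster description, fits fourth-corner
    trait-environment binomial models with AICc subset selection and a
    site-block resampling ANOVA, ordinates sites by environment with
    interpolated growth-form cover surfaces, and models percentage bare
    ground as a degradation indicator. Includes a seeded synthetic survey
    generator with ground truth so every stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
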