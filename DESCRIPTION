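Package: sfsi
Title: Soil Fertility Susceptibility Index for Crop Genotype Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening crop genotypes for tolerance to low soil
    fertility from two-treatment (low/high input) field trials. Computes
    percent trait reduction, soil fertility (stress) intensity, and the
    Fischer-Maurer-type soil fertility susceptibility index (SFSI) per
    genotype; classifies genotypes as tolerant, intermediate or susceptible
    relative to a check variety; runs the supporting trial statistics
    (split-plot linear mixed model analysis of deviance, per-genotype
    Welch tests, Dunnett many-to-one comparisons against the check, and
    Pearson trait correlations); and simulates split-plot trials with known
    genotype-level truth for validation and power studies. Ships the
    genotype-mean tables from a two-year white Guinea yam (Dioscorea
    rotundata) fertility trial as a worked reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
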