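Package: thorsonr
Title: Reliability-Filtered Biogeography of Larval Developmental Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test Thorson's rule -- the classical claim that the
    proportion of marine invertebrate species with non-pelagic development
    increases poleward -- as a spatially explicit, reliability-aware pipeline.
    Builds hydrographic summary fields (water-column temperature, mean current,
    dynamic stratification) from gridded series; computes Colwell's
    predictability, constancy and contingency indices on monthly chlorophyll-a
    series; derives metabolic-theory life-history quantities per species
    (shell volumes, growth ratios, calibrated developmental time, fecundity);
    rasterises literature ranges into potential-habitat maps; assembles
    per-pixel developmental-mode proportion maps and filters them by a
    minimum-species-count power criterion and Chao1-based survey completeness;
    and models the filtered proportions with spatial-lag (SAR) regressions and
    trait structure with mixed models. A seeded synthetic-world generator with
    stored ground truth makes every stage, including the sampling-artefact
    experiment, testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    lme4,
    glmmTMB,
    geosphere,
    generics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
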