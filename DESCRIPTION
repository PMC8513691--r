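Package: tephra
Title: Contamination-Aware Amplicon Community Analysis for Low-Biomass Subsurface Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for 16S rRNA amplicon community analysis of low-biomass
    subsurface samples where drilling-fluid carryover, seawater inflow and
    reagent contamination confound the signal. Implements a three-stage
    decontamination cascade (prevalence test against negative controls,
    taxonomy screening, and a geologically informed four-group set-overlap
    classifier), alpha and beta diversity with rarefaction, NMDS ordination,
    PERMANOVA with pairwise comparisons, environmental vector fitting, and a
    simplified negative-binomial Wald differential-abundance test. A synthetic
    community generator with ground-truth labels supports validation of the
    full pipeline.
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
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
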