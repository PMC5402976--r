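Package: pddasim
Title: Population Density-Dependent Developmental Acceleration in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generative simulation and statistical analysis of population
    density-dependent acceleration of development (Pdda) in Caenorhabditis
    elegans. Provides a plate-level simulator of time to first egg laying
    under isolation versus high-density rearing, built on a push-pull model
    in which an accumulating worm-excreted signal accelerates development
    while chemosensed ascaroside pheromones counteract it; the Pdda percent
    metric with propagated uncertainty, Welch tests and Bonferroni
    correction; ordinal larval-stage comparisons with conversion of stage
    shifts into hours of developmental lead; and adult lifespan analysis
    (Kaplan-Meier product-limit estimation and log-rank tests implemented
    from first principles) under rearing protocols that separate larval
    from adult crowding. Includes CSV schemas for worm-level records and a
    one-call in-silico reproduction of the full experiment suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
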