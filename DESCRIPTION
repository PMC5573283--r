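Package: plasmidrift
Title: Stochastic Simulation and Inference for High-Copy Plasmid Maintenance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generation-based Monte Carlo simulation of plasmid copy-number
    distributions in growing bacterial populations, covering stochastic
    replication failure, uneven partition of plasmid units at cell division,
    and post-segregational killing of plasmid-free cells. Includes grid-search
    fitting of the replication-failure and partition parameters to observed
    plasmid-stability curves, densitometric quantification of plasmid multimer
    distributions from gel lane profiles via an asymmetric-peak model, and
    correction of droplet-digital-PCR copy numbers by mean multimer rank.
    Synthetic-data generators emulate the colony-scoring stability assay and
    densitometry traces so every analysis is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
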