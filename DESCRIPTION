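Package: zwscreen
Title: Female-Specific Marker Discovery from Pooled Gonad RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering W-linked (female-specific) transcripts in
    species with ZW/ZZ sex determination from pooled-gonad RNA-seq, and for
    turning candidates into PCR sexing assays. Includes a seeded synthetic
    ZW transcriptome and count-matrix generator with negative-binomial noise,
    a female-exclusivity screen with a penalised two-model differential
    expression posterior, nearest-neighbor melting-temperature primer design
    under multiplex constraints, species-diagnostic allele-specific primer
    design with in-silico PCR, molecular-clock divergence dating from
    p-distances, and marker-phenotype concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
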