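Package: soilcomm
Title: Soil Microbiome Community Structure: Rarefaction, Diversity,
    Co-Occurrence Networks, Keystone and Indicator Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for amplicon-based soil microbiome surveys
    across land-use strata. Provides even-depth rarefaction of OTU count
    tables, Hill-number and Faith phylogenetic alpha diversity, per-stratum
    Spearman co-occurrence network construction with topology metrics and
    threshold-based keystone-taxon identification, group-equalized
    correlation-based indicator species analysis with a permutation null,
    functional-guild read-count aggregation, and a planted-structure
    community simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
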