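Package: paleotherm
Title: Inference of Fossil Tetrapod Thermophysiology from Apatite Oxygen Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for inferring endothermy versus ectothermy in fossil
    tetrapods from stable oxygen isotope compositions of bone and tooth
    apatite. Screens bioapatite samples for diagenetic alteration using
    structural carbonate content and carbonate-phosphate isotopic offsets,
    aggregates phosphate delta-18-O per taxon and locality with propagated
    analytical uncertainty, forms co-located taxon-pair differences, builds
    theoretical difference envelopes versus palaeolatitude from a
    phosphate-water isotopic thermometer and a latitudinal temperature
    gradient, and classifies each pair as endotherm-like, ectotherm-like or
    ambiguous. Includes a seeded forward simulator with known ground truth so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
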