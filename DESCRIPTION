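Package: decstrat
Title: Time-Stratified Dispersal-Extinction-Cladogenesis Models for
    Historical Biogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of geographic range evolution on
    time-calibrated phylogenies under the dispersal-extinction-cladogenesis
    family of models (DEC, DIVALIKE, BAYAREALIKE) with optional founder-event
    (+J) speciation, time-stratified dispersal-multiplier matrices encoding
    paleogeographic scenarios, AICc model comparison across a scenario-by-model
    grid, and marginal ancestral-range estimation at internal nodes.  Includes
    a forward simulator (Yule chronograms plus Gillespie range evolution) for
    testing and parameter-recovery experiments, utilities for concatenating
    per-locus alignments into partitioned supermatrices, and a packaged
    worked example on Neotropical magnolias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
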