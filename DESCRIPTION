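Package: herdsim
Title: Deterministic Simulation of Selection and Crossbreeding in a National Dairy Herd
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A deterministic, cohort-based model of concurrent within-breed
    selection and between-breed crossbreeding in a seasonal national dairy
    population such as New Zealand's. The package implements an economic
    selection index (breeding worth) over milk, fat, protein and live weight,
    truncation selection across overlapping age classes, a progeny-test bull
    pipeline, gene-fraction tracking of Holstein-Friesian, Jersey and Ayrshire
    ancestry with heterosis, and nine national mating strategies
    (straightbreeding, upgrading, two- and three-breed rotation, and use of the
    best bulls regardless of breed). Annual genetic and phenotypic summaries
    support trend estimation and predicted-versus-actual comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
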