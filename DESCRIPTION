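Package: curtainr
Title: Single-Molecule DNA Curtain Analysis of Homology Search and
    Recombination Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing single-molecule DNA-curtain experiments on
    Rad51/Rad54 presynaptic complexes and the red/white colony assay for
    mitotic recombination outcomes. Includes a synthetic-data generator for
    three-colour kymographs of motor proteins translocating on doubly
    tethered lambda DNA, kymograph track segmentation with velocity and
    distance estimation, Gaussian-mixture population fitting, RPA
    colocalization and intensity-based stoichiometry analysis, homology
    search target-enrichment scoring, and a crossover/non-crossover/
    break-induced-replication colony classifier with replicate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
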