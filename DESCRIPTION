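Package: derepms
Title: Dereplication of Labeled Polyphenolic Mixtures by High-Resolution
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dereplicating complex natural polyphenolic mixtures
    from high-resolution (FTICR) mass spectrometry peak lists. Assigns CHO
    molecular formulae to negative-mode [M-H]- spectra by constrained
    exhaustive enumeration, detects isotopic-labeling peak series
    (H/D exchange, deuteromethylation, deuteride reduction, bromination)
    and converts them into functional-group descriptors, identifies
    deuterium-labeled exogenous components in tissue-extract spectra,
    profiles solvent fractions (van Krevelen ratios, aromaticity-index
    compound classes, target-component enrichment), and filters candidate
    structures (SMILES) against the MS-derived formula and functional-group
    constraints. Includes seeded synthetic-data generators so every pipeline
    stage can be exercised against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
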