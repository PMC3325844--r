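Package: phaomics
Title: Chemostat Physiology and Multi-Omics Reduction for
    PHA-Producing Pseudomonas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of dual-nutrient-limited chemostat
    cultures of polyhydroxyalkanoate (PHA) producing Pseudomonas putida:
    elemental carbon/nitrogen accounting, biomass yield coefficients,
    specific production rates, Egli-model dual-limitation regime
    boundaries, carbon mass balance and steady-state detection; GC-based
    PHA monomer quantification; differential-expression reduction for
    two-channel arrays and 2-D gel spot tables with Benjamini-Hochberg
    FDR control; GC-MS metabolite annotation by Kovats retention index
    and spectral match factor with internal-standard normalization; and
    a seeded synthetic-study generator with known ground truth for
    offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
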