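Package: gapmerTox
Title: Sequence-Based Prediction of Acute Neurotoxicity for LNA Gapmer
    Antisense Oligonucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the acute neurotoxic potential of
    LNA-modified, phosphorothioate antisense oligonucleotide (ASO) gapmers
    after intracerebroventricular dosing. Implements an annotated-gapmer
    sequence dialect (uppercase = LNA, lowercase = DNA), base-composition
    and G-free end-stretch feature extraction, a weighted linear sequence
    score fitted by ordinary least squares to spontaneous calcium
    oscillation scores measured in neuronal cells, tolerability-class
    binning and classifier evaluation (ROC/AUC, accuracy-versus-cutoff,
    confusion metrics), scoring of FLIPR calcium-oscillation fluorescence
    traces with sigmoidal concentration-response fitting, and a
    mismatch-tolerant transcriptome screen used to design G-free
    negative-control gapmers with low neurotoxic potential. A seeded
    synthetic-data generator emulates the statistical structure of the
    training, test and validation panels so the full pipeline can be
    exercised and validated without proprietary screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
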