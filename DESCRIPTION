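Package: resoGGA
Title: Acoustic-Resonance Spectral Classification with a Grouping Genetic
    Algorithm and Extreme Learning Machine
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying liquid mixtures from audible
    acoustic-resonance recordings. Raw ticking-excited WAV recordings are
    segmented into overlapping windows, converted to periodogram power
    spectral densities, cepstrally smoothed, decimated onto a fixed
    1310-point frequency grid and min-max normalized. A wrapper feature
    selection then searches for a small group of discriminative
    frequencies with a Grouping Genetic Algorithm whose fitness function
    is the held-out classification rate of an Extreme Learning Machine.
    Includes a synthetic-data generator with planted informative
    frequencies for method validation, stratified train/test/validation
    splitting, a repeated-validation battery and per-class spectral
    pattern tables. Datasets are held in SummarizedExperiment containers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
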