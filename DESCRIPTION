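Package: dnacontext
Title: Context-Dependent Prediction of DNA Bases and Periodicity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the probability of a DNA base given its flanking context:
    count-based central models (both flanks), order-k Markov models (left
    flank), and a small convolutional + bidirectional-LSTM neural predictor
    sharing a common prediction contract. Includes evaluation machinery
    (annotation-stratified accuracy, reference-base probability arrays,
    model-vs-model density grids, Vuong likelihood-ratio tests for non-nested
    models) and a windowed Fourier pipeline that scans per-base arrays
    (reference-base probabilities, GC/AT indicators) for nucleosome-scale
    periodic signals, with shuffle and randomization controls. A synthetic
    genome generator with known Markov structure, planted periodic GC
    modulation, soft-masked repeats and N blocks provides exact oracles
    (Bayes accuracy, conditional entropy) for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'sequence-io.R'
    'count-models.R'
    'neural-model.R'
    'synthetic-data.R'
    'spectral.R'
    'evaluation.R'
    'cli.R'
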