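Package: zdnascan
Title: Nucleotide-Resolution Prediction and Annotation of Z-DNA Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts functional Z-DNA (left-handed DNA) regions at nucleotide
    resolution by combining DNA sequence with genome-wide omics feature tracks
    (histone marks, transcription factor and RNA polymerase binding, chromatin
    accessibility) and dinucleotide B-Z transition energies. Frames the task as
    per-nucleotide segmentation with convolutional, recurrent (bidirectional
    LSTM) and hybrid neural architectures trained by RMSprop, provides a
    run-length encoded container for genome-length feature tracks, stratified
    windowing and cross-fold whole-genome annotation with probability
    averaging, F1-maximising thresholding and helix-turn (11 bp) join/skip
    region assembly, and model interpretation through L1-pruned first-layer
    feature importance and constrained input maximisation that extracts a
    position weight matrix over the receptive field. Ships a synthetic fixture
    generator with planted Z-prone motifs and correlated feature tracks so the
    whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
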