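Package: deepcnf
Title: Deep Convolutional Neural Fields for Protein Secondary Structure
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence labelling of protein secondary structure with a deep
    convolutional neural field: a linear-chain conditional random field whose
    node potentials are produced by a multi-layer windowed (convolutional)
    neural network over per-residue profile features.  Provides exact
    forward-backward inference and Viterbi decoding in log space, analytic
    gradients for all parameter classes, full-batch L-BFGS training with L2
    regularization and optional layer-wise supervised pretraining, parsers for
    FASTA sequences, PSI-BLAST ASCII profile matrices and DSSP-derived label
    strings, the Q3/Q8 and SOV'99 evaluation metrics, and a seeded synthetic
    data generator with a Bayes-rate oracle so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
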