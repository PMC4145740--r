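Package: snoKSRC
Title: S-Nitrosylation Site Prediction by Kernel Sparse Representation
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts protein S-nitrosylation sites from cysteine-centered
    21-residue peptide windows. Each window is encoded as a 666-dimensional
    feature vector combining evolutionary conservation (PSSM), amino-acid
    factor scores, predicted secondary structure and solvent accessibility,
    flank residue frequencies, and residue disorder scores. Features are
    ranked by minimum-Redundancy-Maximum-Relevance (mRMR) mutual-information
    scoring and the optimal prefix is chosen by incremental feature selection
    under cross-validated Matthews correlation. Classification is by sparse
    representation: orthogonal matching pursuit over a dictionary of training
    samples, either in the raw feature space (SRC) or in a Laplacian-kernel
    induced space via the Gram-matrix linear system (KSRC). Includes a
    synthetic-data generator for end-to-end testing and a command-line
    interface over all pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
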