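Package: embalign
Title: Embedding-Based Pairwise Protein Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise protein sequence alignment in which the residue match
    score is the scaled cosine similarity between per-residue contextual
    embeddings from a protein language model, rather than a substitution
    matrix lookup. Provides affine-gap Smith-Waterman (local) and
    Needleman-Wunsch (global) dynamic programming over arbitrary
    position-specific score matrices, classical substitution-matrix scoring
    as a baseline, extraction of pairwise reference alignments from curated
    benchmark multiple sequence alignments, sum-of-pairs and F1 alignment
    quality metrics with identity and length binning, and a synthetic
    embedding generator with planted alignments so the whole pipeline is
    testable without downloading a language model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
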