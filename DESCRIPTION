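Package: seqanon
Title: k-Anonymous DNA Sequence Obfuscation via an IUPAC Generalization
    Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Protects genomic privacy in sets of highly similar DNA
    sequences by k-anonymous sequence obfuscation. Sequences are grouped
    into clusters of at least k members by iterative similarity search
    with an exact lattice-cost global aligner, and each cluster is
    replaced by a single generalized sequence in which differing
    nucleotides are lifted to their lowest common ancestor in the IUPAC
    ambiguity-code generalization lattice. Information loss is measured
    as the lattice distance between members and the generalized
    sequence. Includes exact minimum-weight perfect-matching and greedy
    pairing baselines, a seeded synthetic-dataset simulator for two
    benchmark-like regimes, an evaluation harness, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'lattice.R'
    'alignment.R'
    'baselines.R'
    'classes.R'
    'clustering.R'
    'evaluation.R'
    'io.R'
    'seqanon-package.R'
    'simdata.R'
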