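Package: hfactor
Title: H-Factor Quality Assessment for Homology-Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the H-factor, a composite quality indicator for
    ensembles of homology models that mimics the role of the
    crystallographic R-factor. Four component scores -- agreement between
    the predicted secondary structure of the target and the observed
    secondary structure of the template, target/template sequence
    identity, structural heterogeneity of the model ensemble, and
    domain-level structural consistency against reference domain
    structures -- are each mapped to a 0-10 scale and aggregated to a
    percentage (0 best, 100 worst). Includes readers for PDB Calpha
    traces, FASTA/Clustal alignments, psipred ss2/horiz predictions,
    stride/DSSP assignments and HMMER domain tables, a Kabsch
    superposition and average-model engine, a deterministic synthetic
    fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
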