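Package: ptrnet
Title: Predicting Protein Abundance from Transcript Abundance and Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the per-gene linear relationship between
    transcript abundance (TPM) and protein abundance (iBAQ) across tissues,
    and for predicting its parameters from gene sequence. Provides matched
    expression-table preprocessing (FPKM to TPM conversion, detection
    thresholds, log2 transform, coverage-based gene partitioning), sequence
    feature encoders (codon, nucleotide and amino-acid counts, start- and
    stop-codon context windows, padded one-hot matrices), a trainable
    two-branch network with dense and convolutional front-ends and a
    NaN-safe mean-squared-error loss, per-gene regression baselines,
    motif discovery from learned convolutional filters via density-based
    (OPTICS) clustering, a cross-validated gene-gene cross-correlation
    screen for context regulators, and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
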