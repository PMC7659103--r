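Package: mybfam
Title: Genome-Wide MYB Gene Family Mining, Duplication, Evolution and
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("mybfam", "developers", email = "mybfam@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide analysis of the MYB
    transcription-factor family in plant genomes, with hexaploid
    (A/B/D subgenome) genomes as the motivating case. Detects ~52-residue
    MYB DNA-binding repeats in proteomes with a log-odds position score
    matrix (or ingests HMMER domtblout tables), classifies genes into
    1R/2R/3R/4R subfamilies and assigns systematic names by chromosomal
    order; calls tandem duplication clusters and collinear segmental
    duplication blocks from pairwise similarity evidence; estimates Ka/Ks
    by Nei-Gojobori (1986) counting with Jukes-Cantor correction; builds
    neighbor-joining trees with bootstrap support; screens
    stress-responsive members from TPM expression matrices with Z-score
    normalization and fold-change/p-value rules; and computes qPCR
    2^-ddCt relative expression. Ships synthetic genome and expression
    generators with machine-readable planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
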