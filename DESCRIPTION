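Package: microProteinR
Title: Prediction of microProteins and Their Target Transcription Factors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts microProteins (miPs) - small, truncated
    transcription-factor-like proteins that retain a protein-protein
    interaction domain but lack a DNA-binding domain - and their putative
    target transcription factors from a whole-proteome FASTA file. The
    pipeline combines a stringent homology search against proteins shorter
    than 550 amino acids with a permissive search against proteins shorter
    than 200 amino acids rescued by a reverse search against the query set,
    then removes candidates that carry DNA-binding domains, exceed 1.1 times
    the length of every target, or carry domains absent from all targets.
    Includes a built-in Smith-Waterman search engine with Karlin-Altschul
    E-values, adapters for precomputed BLAST tabular and InterProScan TSV
    files, a seed-deterministic synthetic-proteome benchmark generator with
    planted miPs and decoys, and recall-driven E-value threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: SequenceMatching, Alignment, Proteomics, FunctionalPrediction
RoxygenNote: 7.3.3
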