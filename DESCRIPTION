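Package: cisRegNet
Title: Cis-Regulatory Network Reconstruction from Expression Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs transcription-factor to target-gene regulatory
    networks from replicate expression profiles. Differentially expressed
    genes are called by signal-ratio thresholds with a Welch t-test,
    annotated by Fisher/hypergeometric gene-set enrichment, and their
    promoters (-3000..+500 around the TSS) are mined for discriminative
    motifs against a matched non-differential background set. Candidate
    binding sites are filtered by a two-state conservation hidden Markov
    model over multi-species promoter alignments, matched to a PWM
    database with empirical similarity p-values, assembled into a directed
    TF-target network ranked by PageRank, and verified by 2^-ddCt qPCR
    quantification. A seeded synthetic-data generator with full ground
    truth makes every stage testable without external downloads.
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
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
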