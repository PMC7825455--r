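Package: curvestage
Title: Growth-Curve Staging and Stage-Profiled Muscle Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits three-parameter sigmoid growth models (logistic, Gompertz,
    Von Bertalanffy) to longitudinal body-weight records, derives the three
    growth-curve inflection points (GRI, MGI, RSI) in closed form from the
    second and third derivatives, and partitions the trajectory into the
    gradually, rapidly and slowly increasing stages. Around the staging it
    implements a stage-profiled skeletal-muscle RNA-seq workflow: CPM-based
    expression filtering, log2(CPM+1) sample structure analyses (hierarchical
    clustering, PCA), a negative-binomial Wald test for stage-versus-stage
    differential expression with Benjamini-Hochberg FDR, 100-kb cis-window
    assignment of protein-coding targets to lncRNAs, and a candidate-lncRNA
    screen (Pearson correlation panels, 2^-ddCt quantification, miRNA
    seed-match scanning with a dinucleotide-shuffle null). Seeded synthetic
    generators emulate every input so the full workflow runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    ape,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
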