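Package: npmine
Title: Neuropeptide Precursor Mining, Annotation and Copy-Number Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and annotating neuropeptide precursor
    (preprohormone) proteins in transcriptome data: six-frame translation and
    ORF extraction around local-alignment hits, a desk-scale translated
    Smith-Waterman search with a Karlin-Altschul E-value contract, prediction
    of N-terminal signal peptides and mono-/dibasic prohormone-convertase
    cleavage sites, calling of mature peptides with C-terminal amidation and
    N-terminal pyroglutamation, species-by-family peptide copy-number matrices
    with clade-level summaries, outlier flagging and cleavage-site knockout
    scanning in multiple alignments, an all-vs-all similarity graph with a
    seeded force-directed embedding, and a fully seeded synthetic-precursor
    generator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
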