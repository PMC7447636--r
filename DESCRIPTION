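Package: fusionscope
Title: Characterization of Protein Kinase and Transcription Factor Gene Fusions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for characterizing oncogenic gene fusions
    detected in cancer transcriptomes. Assembles fusion transcripts from
    breakpoint calls against gene models, predicts reading-frame effects and
    fusion protein sequences, classifies protein kinase (PK) and transcription
    factor (TF) fusions, assesses full-length retention of wild-type protein
    domains and their PK/TF specificity, builds maximal foreseeable interactor
    sets from physical protein-protein interaction data with pathway-hierarchy
    distance mapping, and runs a replicated random-control negative-binomial
    differential-expression procedure with pathway over/under-expression
    z-scores. A synthetic-data module generates every pipeline input with
    known ground truth so the whole workflow is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    edgeR,
    limma,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
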