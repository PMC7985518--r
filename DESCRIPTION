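Package: tfcascade
Title: Hierarchical Classification of Primary and Secondary Transcription
    Factor Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies ligand-responsive genes into primary and secondary
    targets of a root transcription factor (such as the vitamin D receptor)
    by combining three evidence channels: ChIP-seq peaks in a window around
    the transcription start site, peaks overlapping gene-linked regulatory
    elements (REMs), and biophysical TRAP motif affinities in open chromatin
    aggregated into exponentially decaying TF-gene scores. Ranks candidate
    driver transcription factors of the secondary response with a sparse
    (elastic net) logistic regression on condition-contrasted TF-gene scores
    and assembles a directed, root-centred transcription factor network.
    Includes a deterministic generator of miniature regulatory landscapes
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
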