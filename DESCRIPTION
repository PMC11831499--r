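Package: nodcerna
Title: Whole-Transcriptome Nodulation ceRNA Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis of coding and noncoding RNA regulation
    during legume root nodulation: count normalization (FPKM, TPM,
    trimmed-mean scaling factors), exact negative-binomial differential
    expression with Benjamini-Hochberg correction, classification of
    nodulation-regulated (NR) and nodulation/NARK-regulated (NNR) RNA sets,
    weighted co-expression module detection with scale-free soft-threshold
    selection, lncRNA biotype classification and cis-target inference,
    plant-style miRNA response-element scanning, and inference of
    lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA) triplets. A synthetic
    data generator plants known differential-expression effects,
    co-expression modules, and ceRNA triplets under the 2-genotype x
    3-tissue x 2-treatment x 3-replicate study design so every stage is
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
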