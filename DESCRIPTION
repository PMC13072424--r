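Package: chrombsr
Title: Chromatin-State Segmentation and Breed-Specific Enhancer Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparative muscle epigenomics in
    crossbred versus purebred sheep. Segments the genome into 15 chromatin
    states from five binarized epigenetic marks (ATAC, H3K4me3, H3K27ac,
    H3K4me1, H3K27me3) with a multivariate Bernoulli hidden Markov model,
    identifies breed-specific active enhancers from replicate-consistent
    binary scoring over a consensus enhancer set, performs negative-binomial
    differential expression with fold-change and TPM filters, quantifies
    chromatin-state enrichment in differentially expressed gene territory,
    assigns enhancers to target genes proximally and through chromatin
    loops, and builds a thresholded co-expression hub network. A synthetic
    epigenome generator with planted ground truth (breed-specific
    enhancers, differentially expressed genes, enhancer-gene links) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
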