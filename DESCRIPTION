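Package: germquant
Title: Nascent-Germline Transcript Quantification and X-Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying transcripts in nascent C. elegans germlines
    and testing X-chromosome misregulation. Counts single-molecule FISH spots
    in 3D image stacks by Laplacian-of-Gaussian enhancement, threshold-plateau
    selection and regional-maxima detection inside GFP-segmented primordial
    germ cells; performs low-input negative-binomial Wald differential
    expression with pooled-deconvolution size factors and log-fold-change
    shrinkage; runs hypergeometric gene-set and chromosome enrichment, Venn
    overlaps and exact 2x2 tests on germline-health tables; and prioritizes
    transcription-factor candidates from ChIP peak-to-promoter assignment and
    position-weight-matrix scanning. A synthetic-data module generates image
    stacks, count matrices, peaks, promoters and motifs with known ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    withr,
    jsonlite,
    tiff,
    EBImage,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
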