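Package: rerepseq
Title: Detection of Heterochromatic DNA Re-Replication and Transposon
    Derepression from Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting heterochromatic DNA
    re-replication from binned genomic read coverage (pseudocounted
    score tracks, log2 mutant/wild-type ratios, sliding-window Z-score
    segmentation, region merging and transposable-element annotation),
    for calling transcriptional derepression of transposons from
    RNA-seq counts (RPKM, Fisher's exact test with Benjamini-Hochberg
    correction, fold-change and replicate-intersection criteria), and
    for the accompanying summaries: bisulfite methylation levels per
    cytosine context (CG/CHG/CHH), heterochromatin boundary metaplots,
    chromosome-scale smoothed views, and flow-cytometry ploidy-peak
    coefficient-of-variation quantitation. Includes a synthetic-data
    generator with planted ground truth so every stage of the analysis
    can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    rtracklayer,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
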