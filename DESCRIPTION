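Package: napscape
Title: Genome-Wide Occupancy, Expression Dynamics and 3C Quantification
    for a Broad-Binding Nucleoid-Associated Protein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis pipeline for a cyanobacterial
    nucleoid-associated protein (NAP) that binds broad, AT-rich genomic
    tracts. Computes input-normalized ChIP binding signal and sliding-window
    GC content on a common bin grid; derives replicate-consensus narrow
    summits (40 bp merging with control exclusion) and broad binding regions
    (replicate intersection with control exclusion); classifies genes and
    transcriptional units by extent of occupancy; assigns temporal expression
    classes (transient, plateau, continuous, late) from time-course
    log2 fold-change tables; tests occupancy-by-class and summit-by-region
    associations with Fisher's exact test, FDR adjustment and pairwise
    Wilcoxon rank-sum tests; and quantifies 3C-qPCR interaction frequencies
    by the delta-delta-Ct method with per-locus dilution-series standard
    curves. A synthetic-data generator emulating the study design (AT tracts,
    a broad binder, point-binding sigma factors, planted expression classes
    and interaction profiles) makes the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
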