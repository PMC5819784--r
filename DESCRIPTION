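Package: tagdge
Title: Tag-Based Digital Gene Expression Profiling of Silkworm Egg Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of NlaIII/MmeI 21-bp tag digital gene
    expression (DGE) libraries across a five-point unfertilized-egg time
    course. Builds a virtual CATG+17 reference tag library, cleans and maps
    raw tag libraries with 1-mismatch tolerance, identifies differentially
    expressed genes with the Audic-Claverie exact count test under FDR
    control, clusters log2-ratio time profiles with Pearson-distance
    hierarchical clustering, classifies orthologous maternal genes, detects
    50-kb genomic gene clusters, performs GO over-representation tests, and
    summarizes qPCR cycle-threshold tables by the 2^-ddCT method. A
    synthetic-data generator with planted expression archetypes provides a
    fully specified ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    igraph,
    jsonlite,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
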