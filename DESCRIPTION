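Package: dictyComp
Title: Comparative Genomics and Developmental Transcriptomics of Social Amoebae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a cross-species comparative
    framework for dictyostelid social amoebae: reciprocal (bidirectional)
    best-hit orthology from BLAST tabular hit tables with four-species
    Venn-area decomposition, gene-family assignment by homology propagation
    with lineage-dependent expansion flagging, and a developmental
    time-course comparison pipeline (RPKM conversion, replicate averaging,
    per-timepoint scaling to a common total, unexpressed-gene filtering,
    per-gene standardization, collective K-means clustering under Pearson
    correlation distance with multi-restart selection, two-group cluster
    partitioning, and ortholog-pair concordance classification into match,
    similar, precocious and retarded classes). Includes a synthetic-data
    generator with planted ground truth (ortholog presence patterns, family
    expansions, temporal archetypes and concordance classes) so the whole
    pipeline is testable end to end, plus a file-based stage driver with
    provenance records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
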