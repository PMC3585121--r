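Package: alkaloci
Title: Comparative Genome Architecture of Fungal Alkaloid Biosynthesis Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the genome architecture of secondary-metabolite
    (SM) gene clusters in clavicipitaceous fungi: de novo discovery of
    multicopy repeat families from genome self-alignment and their
    correspondence across genomes, RIP (repeat-induced point mutation) index
    profiling in sliding windows, detection of MITEs by terminal inverted
    repeats and of terminal telomere repeat arrays, delimitation of SM gene
    clusters around signature biosynthesis genes using a primary-metabolism
    ortholog rule, refinement of ortholog groups by bootstrapped bipartition
    with a split-score acceptance rule, and rule-based prediction of alkaloid
    chemotypes (ergot alkaloids, indole-diterpenes, lolines, peramine) from
    per-genome gene status. Includes a synthetic-genome generator that plants
    transposon relics, RIP-mutated copies, MITEs, telomere arrays and SM
    clusters with known ground truth, so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
SystemRequirements: NCBI BLAST+ (makeblastdb, blastn) on PATH for
    self-alignment, masking and cross-genome repeat correspondence; mafft
    (optional) for aligning unequal-length ortholog-group members.
Config/testthat/edition: 3
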