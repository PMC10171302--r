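Package: anfscreen
Title: Screening Bacterial Genomes for Antinutritional-Factor Metabolism Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A catalog-driven pipeline for screening annotated bacterial
    genomes for genes that eliminate antinutritional factors (ANFs) in
    plant-based feed and food: phytate, tannins, phenolic acids, lectins,
    trypsin inhibitors, saponins and alpha-galactooligosaccharides.
    Detects catalog enzymes by annotation keywords and global protein
    alignment, builds reciprocal-best-hit ortholog clusters, constructs
    binary gene presence/absence matrices with per-genome ANF profiles and
    core/dispensable/singleton pan-genome partitions, clusters genomes by
    binary gene content (UPGMA), and selects strain consortia that maximise
    joint ANF-elimination capacity. Includes a deterministic synthetic
    genome generator with planted genes and a ground-truth table for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    ape,
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
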