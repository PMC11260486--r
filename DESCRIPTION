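Package: linchrom
Title: Chromosome Architecture Analysis for Linear Actinomycete Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the architecture of linear bacterial
    chromosomes, built around the genome organisation of filamentous
    Actinomycetia (Streptomyces in particular). Detects and measures
    terminal inverted repeats by end-anchored banded self-alignment,
    orients chromosomes by the dnaA gene, computes center-relative
    placement densities of core genes and biosynthetic gene cluster
    protoclusters, estimates Mash (MinHash) genome distances and
    delineates computational species by Louvain community detection on a
    similarity network, and classifies extrachromosomal replicons as
    plasmids from marker-domain content. Includes a synthetic-genome
    generator with machine-readable truth tables for validating every
    step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
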