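Package: asmcurate
Title: Post-Assembly Curation of Heterozygous Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating de novo genome assemblies of highly
    heterozygous diploid organisms. Implements k-mer spectrum genome-size
    estimation, whole-genome self-alignment with exact anchors, chaining of
    fragmentary alignments by a weighted longest-increasing-subset dynamic
    program, coverage-based removal of redundant heterozygous contigs
    (haplotigs) with an identity-based restore rule, mitochondrial and
    taxon-annotated GC-coverage contamination filters, Illumina read
    cleaning, MISA-style microsatellite detection and genetic-marker
    selection, assembly summary statistics (N50/N90, GC, consensus QV), and
    a diploid assembly simulator with known truth labels for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
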