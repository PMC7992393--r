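Package: oystr
Title: Assembly Curation and Rolling-Circle Transposon Annotation for
    Highly Heterozygous Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for curating diploid-grade genome assemblies of
    highly heterozygous species (such as the Pacific oyster) and for
    structure-based annotation of Helitron/Helentron rolling-circle
    transposable elements. Provides k-mer spectrum profiling with
    genome-size and heterozygosity estimation, iterative length-ordered
    haplotig purging with a minimizer-based internal mapper,
    coverage-based assembly quality control with GC normalization,
    structural-variant error filtering, linkage-map scaffold anchoring,
    a structural screen for Helitron termini (TC...CTAG with a
    sub-terminal hairpin and AT target-site context), Helentron
    substructure classification, 3'-end family clustering, gene-fragment
    capture screening, and window-based density statistics. Includes a
    synthetic-genome simulator with planted ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
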