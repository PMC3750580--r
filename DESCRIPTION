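Package: hgtscan
Title: Detection of Horizontal Gene Transfer by Homology Filtering and
    Phylogenetic Nesting
Version: 0.9.0
Authors@R:
    person("HGTScan", "Developers", email = "hgtscan@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for genome-wide detection of horizontally
    transferred genes in a eukaryote: a three-step homology filter cascade
    on translated similarity hits, neighbor-joining phylogenies with
    bootstrap support and a donor-clade nesting classifier, verification of
    genomic integration by contig mapping and read-coverage bias testing,
    structural analysis of transferred segments (co-transfer, lost
    intergenic DNA, intron detection, operon heuristics), Nei-Gojobori
    dN/dS estimation with significance testing, and FPKM-based
    differential expression across developmental stages.  A synthetic-data
    generator with planted transfer events provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
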