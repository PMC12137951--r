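Package: popgenscan
Title: Windowed Population-Genomic Scans, Diversity Statistics and SSR
    Mining for Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-genomic analysis of small diploid resequencing
    panels from a multi-sample VCF: site filtering (quality, depth,
    indels, missingness, minor-allele frequency) and windowed LD pruning;
    nucleotide diversity and per-individual inbreeding coefficients;
    windowed Weir-Cockerham F_ST with a two-contrast outlier-region scan
    and gene intersection; neighbour-joining phylogenies with SNP-column
    bootstrap; microsatellite (SSR) mining of a reference FASTA; and a
    Balding-Nichols genotype simulator with known truth for end-to-end
    validation of every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    jsonlite,
    methods,
    S4Vectors,
    phytools,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
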