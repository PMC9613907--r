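Package: islescan
Title: Allele-Sharing Genome Scans for Island-Specific Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed genome scans built on allele-sharing (matching)
    matrices: population-specific and pairwise FST in the Weir-Goudet
    moment framework, nucleotide diversity and absolute divergence (dxy),
    blocked linkage-disequilibrium summaries, five-sigma outlier region
    calling with gene annotation, population diversity summaries
    (heterozygosity, private alleles with rarefaction, inbreeding
    coefficients), and an Outlying Mean Index (OMI) climatic-niche
    ordination. Includes a seeded Balding-Nichols simulator with a
    plantable swept haplotype so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
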