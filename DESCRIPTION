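Package: pedhap
Title: Pedigree Haplotype Blocks, Graphical Genotypes and Diversity in Inbred Crop Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SNP-array analysis of closely related inbred crop
    cultivars: array quality-control filtering, genotype coding against two
    reference cultivars, graphical genotypes with midpoint cell borders,
    identity-by-state pedigree haplotype blocks and their ancestral
    attribution, consensus blocks among progeny, Lewontin D-prime
    linkage-disequilibrium decay profiles, sliding-window haplotype
    diversity indices with Friedman group comparison, synonymous versus
    non-synonymous SNP classification against CDS models, and per-chromosome
    SNP density summaries. Includes a breeding-program simulator (Haldane
    recombination, single-seed-descent selfing) with full founder-of-origin
    truth tracking for validating the block-recovery machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
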