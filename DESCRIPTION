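Package: rsnpcoseg
Title: Co-Segregation Scanning of Regulatory SNPs and GWAS Window Mapping
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-GWAS prioritization of regulatory SNPs (rSNPs) from a
    population genotype panel. Genotypes are binarized against the panel-wide
    minor allele, coding SNPs whose carrier patterns lie improbably close to a
    query rSNP under an XOR (Hamming) distance are called co-segregating
    markers via an exact hypergeometric or permutation null, and rSNPs are
    linked to trait-relevant GWAS catalog signals when the rSNP or one of its
    markers falls within a genomic window of the GWAS SNP. Includes a seeded
    synthetic panel generator (diploid VCF, gene annotation, GWAS-style trait
    table, machine-readable truth file) so the whole pipeline is testable
    without external downloads, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
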