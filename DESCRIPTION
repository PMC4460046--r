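Package: ncsel
Title: Natural-Selection Scans on Genomic Element Partitions of Phased Polymorphism Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Element-partitioned scans for natural selection in phased
    biallelic SNP data. Computes site-frequency-spectrum neutrality
    statistics (segregating sites, nucleotide diversity, Tajima's D,
    Fu and Li's D* and F*, Fay and Wu's H, observed heterozygosity) on
    concatenated genomic elements in 10 kb sliding windows, with
    bootstrap means and permutation tests against a genome-wide
    background; Weir-Cockerham F_ST (global and pairwise over pooled
    populations); minor and derived allele-frequency spectra with
    enrichment tests; GERP-threshold conservation classification;
    an EHH/iHS extended-haplotype scan; and a composite positive-
    selection caller (DAF, F_ST, |iHS|) with gene annotation. Includes
    coalescent-based generators for neutral, island-model, selective-
    sweep, and purifying-selection-skewed haplotype data so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
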