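Package: haploSweep
Title: Selection-Signature Scans from Phased Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects selective sweeps in two-population phased SNP data by
    combining three complementary statistics: the per-SNP Weir-Cockerham
    fixation index (Fst), cross-population extended haplotype homozygosity
    (XP-EHH) with genome-wide z-normalization, and per-site nucleotide
    diversity ratios (log2 theta-pi control/test). Includes variant quality
    control with an exact Hardy-Weinberg test, empirical top-1% outlier
    calling, intersection of outlier SNPs across statistics, construction of
    5-kb flanking candidate regions, gene annotation by interval overlap,
    and a synthetic-data generator that plants hard sweeps with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
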