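Package: sweepscan
Title: Genome-Wide Selective Sweep Scans from Phased SNP Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects signatures of recent directional selection in phased
    SNP-array haplotype panels. Marker pairs are classified by
    likelihood-based confidence bounds on the linkage-disequilibrium
    coefficient D', runs of markers in strong pairwise LD are assembled
    into core regions, and each core haplotype is scored by extended
    haplotype homozygosity (EHH) and relative EHH (REHH) at a fixed
    physical distance on both flanks. Significance is assessed by
    empirical p-values within core-haplotype frequency bins. Includes a
    forward Wright-Fisher simulator of phased haplotype panels (neutral,
    selective-sweep, and divergently selected two-line modes), interval
    annotation of significant regions, and a between-population
    haplotype-frequency contrast test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
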