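Package: t2tscan
Title: Telomere, Centromere, Gene-Cluster and Heterozygosity Annotation for
    Gap-Free Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation toolkit for telomere-to-telomere (gap-free) plant
    genome assemblies. Discovers the telomeric repeat unit and calls telomeres
    at chromosome arms, scans 30-500 bp tandem-repeat (satellite) arrays,
    groups integer-multiple (higher-order) repeat units into monomer families,
    localizes centromeres from satellite density combined with gene/TE
    depletion, extracts genes captured inside centromeres, detects
    domain-seeded tandem gene clusters and resistance-gene architectures, and
    scans multi-sample VCFs for windowed heterozygosity hotspots. Includes a
    seeded synthetic-genome simulator that plants telomeres, centromeric
    satellite arrays, TE-like features, clustered gene models and heterozygous
    SNP hotspots with machine-readable truth, so every caller can be
    benchmarked against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
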