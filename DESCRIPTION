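Package: poolsweep
Title: Pooled-Sequencing Variant Filtering, SNP Density Scans and ZHp
    Selective-Sweep Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis for pooled whole-genome
    sequencing of livestock populations. Applies GATK-style hard filters
    and a genotype-quality mask to multi-pool VCFs, classifies variants
    (SNP/indel, fixed/segregating) and computes the Ti/Tv quality ratio,
    flags variants as novel against a known-variant catalogue, maps
    annotator consequence terms onto functional classes and tabulates
    them per pool, scans 1 Mb windows for SNP-density enrichment, and
    detects selective sweeps from Z-transformed pooled heterozygosity
    (ZHp) in 150 kb sliding windows with 50% overlap. A synthetic
    pool-seq generator produces VCFs, catalogues, consequence tables and
    ground truth so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
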