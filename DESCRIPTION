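Package: gojivar
Title: Variant Spectra, Coding Consequences and Cohort Discrimination for
    Goji Berry Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-call variant analysis for a two-cohort (cultivated versus
    wild) Lycium barbarum resequencing design: depth and mapping-quality
    filtering of SNPs and short InDels, strand-collapsed six-class mutation
    spectra with transition/transversion ratios, per-mille heterozygosity
    rates, InDel length distributions, windowed variant-density tracks,
    splice-aware projection of SNPs onto coding sequence with codon-change
    and amino-acid property classification, and a uniform-state rule that
    identifies variant sites discriminating the two cohorts. Includes a
    deterministic synthetic-data generator (genome, CDS annotation, VCF)
    with configurable spectrum, heterozygosity, InDel length law and
    chromosome-end density enrichment, and packages the published per-gene
    SNP state tables for three BODYGUARD genes as machine-readable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
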