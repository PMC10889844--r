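# gojivar

Post-call variant analysis for a two-cohort goji berry (*Lycium
barbarum*) resequencing design: five cultivated genotypes (Lb1–Lb5)
versus three wild ones (Lb6w–Lb8w), called against the annotated
reference genome. The package is aimed at breeders and population
geneticists who need the standard resequencing summaries plus a
gene-level view of which coding SNPs separate wild from cultivated
material — here, the three *BODYGUARD* (*BDG*) cuticle-biosynthesis
genes used as a case study for stress-resistance breeding.

What it computes:

* **Variant QC** — per-allele splitting of multi-allelic VCF records,
  SNP/insertion/deletion classification, and the strict post-call
  filters: supporting reads > 4 and RMS mapping quality > 20; InDels
  are ≤ 50 bp by definition.
* **Mutation spectra** — the six strand-collapsed substitution classes
  (T:A>C:G, T:A>G:C, C:G>T:A, C:G>A:T, T:A>A:T, C:G>G:C), the
  transition/transversion ratio ts/tv, and the heterozygosity rate
  het‰ = 1000 · n_het / callable bases; InDel length distributions and
  windowed SNP/InDel density tracks.
* **Coding consequences** — splice- and strand-aware projection of SNPs
  into CDS coordinates, codon-change assembly (including multi-SNP
  codons), translation under the standard genetic code, and
  synonymous/missense/nonsense classification with amino-acid polarity
  and charge-change flags.
* **Cohort discrimination** — a site discriminates the cohorts when
  every cultivated sample shares one genotype state class (hom-ref /
  hom-alt / het), every wild sample shares one class, and the classes
  differ.
* **Simulation** — a deterministic generator of genomes, CDS
  annotations and VCFs with configurable spectrum, heterozygosity,
  InDel length law, chromosome-end density enrichment and planted
  discriminating coding sites, so every stage is testable without the
  (unreleased) raw data.

The published per-gene SNP state tables for the three *BDG* genes are
packaged verbatim as text fixtures (`inst/extdata/bdg_sites_*.tsv`)
with an auditable corrections file for their typographic errors.

## Worked example

Fixture-driven analysis of the chromosome-4 *BDG* gene:

```r
library(gojivar)

m   <- read_site_table(bdg_table_paths()[["LOC132634709"]])
coh <- read_cohorts(system.file("extdata", "cohorts.tsv",
                                package = "gojivar"))
gene_discrimination_report(m, coh)
#> <discrimination_report> LOC132634709: 14 of 22 sites discriminate (64%)
#>   non-discriminating: 590, 749, 1208, 1247, 1352, 1439, 1715, 1886
#>                     effect
#> discriminating       silent non_silent
#>   discriminating          6          8
#>   non_discriminating      8          0
```

Fourteen of the 22 coding SNPs separate wild from cultivated genotypes
(64% after half-up rounding); the eight that do not are all silent.
Simulation-driven profiling runs the same machinery end to end:

```r
cfg <- simulation_config(seed = 1, chromosomes = c(chr1 = 2e6, chr2 = 2e6),
                         n_genes = 3, gene_length = 1800)
run_pipeline(simulate = cfg, out_dir = "results/demo")
```

which writes `spectrum.tsv` (per-sample class counts, ts/tv ≈ 1.72,
het ≈ 5.0 ‰ under the defaults), `indel_summary.tsv` (~49% 1-bp
InDels), `density.tsv` and per-gene site tables.

The numbered scripts under `analysis/` are the same workflow as a
narrative: `01_simulate.R` (synthetic study), `02_variant_profile.R`
(spectra, InDels, density), `03_bdg_tables.R` (published gene tables),
`04_parameter_recovery.R` (estimator checks). Each writes under
`results/`.

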