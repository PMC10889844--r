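---
title: "Variant spectra, coding consequences and cohort discrimination in goji berry resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant spectra, coding consequences and cohort discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis

Whole-genome resequencing of goji berry (*Lycium barbarum*) genotypes —
five cultivated accessions (Lb1–Lb5) and three plants collected from wild
populations (Lb6w–Lb8w) — yields per-sample variant calls against the
annotated reference genome. `gojivar` implements the post-call analysis
of such a design:

1. **Variant QC.** Multi-allelic records are split per alternate allele;
   records are classed as SNPs, insertions or deletions; a variant is kept
   only when its supporting read depth is *over* 4 and its RMS mapping
   quality *exceeds* 20 (both comparisons strict, matching the upstream
   mpileup filtering convention), and InDels longer than 50 bp are
   rejected by definition.
2. **Mutation spectra.** A substitution and its reverse complement are
   one event read from opposite strands, so the 12 ordered substitutions
   collapse into six classes (T:A>C:G, T:A>G:C, C:G>T:A, C:G>A:T,
   T:A>A:T, C:G>G:C). Transitions are T:A>C:G and C:G>T:A; the ts/tv
   ratio, the per-mille heterozygosity rate
   (1000 × het calls / callable bases), InDel length distributions and
   windowed density tracks summarise each genome.
3. **Coding consequences.** SNPs are projected through the spliced,
   strand-oriented CDS coordinates of a gene model, grouped by codon
   (several SNPs may hit one codon), assembled into reference/alternate
   codon pairs, translated under the standard genetic code, and classed
   as synonymous, missense, nonsense or stop-loss, with flags for
   polarity (polar ↔ nonpolar) and charge (basic/acidic/uncharged
   crossings) changes of the encoded amino acid.
4. **Cohort discrimination.** At each coding SNP site every sample is in
   one of three state classes — homozygous-reference, homozygous-alternate
   or heterozygous. A site *discriminates* the cohorts when every
   cultivated sample shares one class, every wild sample shares one
   class, and the two classes differ.

The published per-gene SNP tables for the three *BODYGUARD* (*BDG*)
cuticle-biosynthesis genes (chromosomes 4, 8 and 9) are packaged
verbatim as machine-readable fixtures, so the whole coding analysis is
reproducible from the printed state patterns alone.

## The discrimination rule

The rule (both cohorts internally uniform, classes distinct) was induced
from the published discriminating/non-discriminating assignments. It is
the only state-class rule consistent with the chromosome-4 table: for
example position 517 (cultivated all heterozygous, wild all
homozygous-reference) discriminates, while position 590 (cultivated
uniformly homozygous-alternate, wild mixed het/hom-ref) does not. A
looser "state sets disjoint" rule would wrongly admit 590.

One published count cannot be reproduced under any such rule: the
chromosome-8 narrative lists 17 discriminating positions including 799,
but the printed states of the wild cohort at 799 are {het, het,
hom-alt} — not uniform. Positions 799 and 590 are state-symmetric (one
cohort uniform, the other mixed, classes disjoint), so no rule can admit
one and exclude the other. The package reports the rule-based count of
16 for that gene and flags the discrepancy; the other two genes
reproduce the published 14/22 and 15/28 exactly, as do all silent/
non-silent cross-tabulations. Percentages are rounded half-up
(14/22 → 64%).

Sites spanning several printed positions (e.g. "287-288") are treated as
one site; cells may carry per-position tokens ("h14/Lys"), and the site
discriminates if any constituent position does — this reproduces the
published listing of 288 (not 287) among discriminating locations.

## Fixture dialect and corrections

Each fixture is a TSV with the printed columns (position, codon,
amino acid, reference, one column per sample). Cell grammar: `hNN` is a
heterozygous call with NN% alternate-supporting reads; `Xxx(COD)`
resolves a homozygous state by codon; a bare amino acid is matched
against the reference and alternate amino acids. Three interpretation
rules deserve note:

* Effects are always recomputed from the printed codons, never taken
  from the printed amino-acid strings.
* A bare token that matches both states (a silent site printed without
  codons, e.g. position 688 "Asn") is read as the reference state; the
  choice is logged. The alternative (homozygous-alternate) would change
  no published count for 688/694 — both cohorts would still differ.
* Typographic impossibilities are preserved in the fixture and
  normalised at load through an auditable corrections file
  (`table_corrections.tsv`): a reference cell contradicting its printed
  codons (positions 1439 and 1761 on chromosome 4, 824 on chromosome 8)
  and a heterozygous percentage above 100 ("h775", read as h75).
  Printed position ranges that are inconsistent with codon-frame
  arithmetic (555-557, 1671-1672) are kept as printed and logged.

The amino-acid property partition is: nonpolar {Gly, Ala, Val, Leu, Ile,
Pro, Phe, Met, Trp}; polar {Ser, Thr, Cys, Tyr, Asn, Gln}; basic {Lys,
Arg, His}; acidic {Asp, Glu}. Charge changes are crossings between
basic, acidic and uncharged; polarity changes are polar ↔ nonpolar
crossings. Flags are always false for synonymous changes.

## The synthetic-data generator

No raw reads or variant calls are released for the study, so the
generator produces genomes, CDS annotations and VCFs with the
statistical structure the analysis assumes. Its defaults are fixed at
the study conditions:

| parameter | default | rationale |
|---|---|---|
| SNP rate | 0.0084 / base | ~14M SNPs per genome on a 1.67 Gb reference |
| class probabilities | ts share 0.6324 | ts/tv 1.7203 ≈ 1.72; C:G>T:A most frequent, T:A>C:G second, C:G>G:C rarest |
| het rate | 5.037 ‰ | highest observed per-sample rate |
| InDel rate | snp_rate / 10 | SNP:InDel ratio ≈ 10 |
| deletion share | 0.538 | 6.04M deletions vs 5.17M insertions |
| InDel length law | 0.494 / 0.135 / 0.072, geometric(0.8) tail | ~50%/13%/7% at 1/2/3 bp; <1% beyond 12 bp, <0.1% beyond 32 bp |
| end density | 3× in terminal 10% | elevated variation toward chromosome ends |
| filter pass rate | 0.95 | most called sites survive the depth/MQ filters |
| discriminating fraction | 0.55 | ≈ the share observed across the three gene tables |

Design points:

* The T:A-rooted classes sum to probability 0.5, so on a base-balanced
  random genome the realised class frequencies equal the configured ones
  (a class is drawn conditionally on the reference base at the site).
* Positions are drawn without replacement within each density region,
  so site counts are never thinned by collisions and the expected
  heterozygous count is exactly `het_rate × callable bases`.
* The per-sample heterozygosity probability is derived as
  `het_rate / (snp_rate × pass_rate)` so the target is met *after*
  filtering, mirroring the published order (filters first, summaries
  second).
* Discriminating coding sites are planted as (cultivated het, wild
  hom-ref) or (cultivated hom-alt, wild het) with equal probability,
  the two patterns dominant in the published tables; non-discriminating
  sites are all-het or one-cohort-mixed. Background records colliding
  with planted sites are dropped.
* A single RNG stream with documented draw order (per chromosome:
  counts, positions, classes, evidence, then per-sample genotypes) keeps
  earlier draws stable when later stages grow; a fixed seed makes every
  output file byte-identical.

What the generator does **not** emulate: linkage disequilibrium,
demography, read-level errors, indel realignment artefacts, GC bias and
reference Ns. Passing recovery tests therefore demonstrates the
estimators' correctness on clean data, not robustness to real-data
artefacts.

## Numerical choices

* Coordinates are 1-based inclusive throughout (VCF/GFF3 native); the
  density track output alone is 0-based half-open (BED-like).
* `callable_bases()` excludes Ns by default (the "without Ns" reference
  length); a flag includes them, since the published rate definition
  says "total count of genomic bases" while coverage is reported
  N-excluded.
* Heterozygous alt-read fractions come from AD when present and are
  marked unavailable otherwise; the discrimination rule never uses them.
* Multi-nucleotide substitutions are decomposed into per-base SNPs at
  differing offsets; InDels are not re-normalised beyond VCF convention.
* Without per-sample attestation, a multi-SNP codon substitutes all
  group alleles jointly (the printed reading of e.g. AAA→CGA); with
  genotype evidence, only attested allele combinations are enumerated,
  with `full_enumeration = TRUE` available to force the Cartesian space.
* Division by zero transversions reports an absent ratio, not an error.
* The record-level DP is used for the read-support filter, matching
  mpileup output granularity (the per-sample reading is not recoverable
  from record-level calls).

## Problem sizes

The packaged tests and the acceptance script run desk-scale: parameter
recovery uses ~1e5 SNPs (two 6 Mb chromosomes), ~1e5 InDels (10 Mb at
InDel rate 0.01) and a 10 Mb genome for the heterozygosity rate; the
analysis scripts use a 2 × 2 Mb genome with eight samples. Estimator
accuracy at these sizes is set by Monte-Carlo error (≈ ±0.01 on ts/tv,
±0.16 percentage points on the 1-bp share, ±0.022 ‰ on the het rate,
one standard error), far tighter than the biological differences the
study reports.

## Limitations

* The discrimination rule is descriptive, not inferential: with three
  wild samples no association test is meaningful, and none is computed.
* Phase is unknown; attested codon combinations are a conservative
  lower bound on haplotypes.
* The published narrative percentages for chromosomes 8 and 9 (69%, 56%)
  do not match their own printed fractions (17/26, 15/28) under any
  rounding; counts, not percentages, are treated as authoritative.
* Genome-wide totals published for the original eight genomes depend on
  unreleased raw data and are out of reach; only their summary
  statistics (ratios, rates, distributions) are reproduced, by
  simulation at configured values.
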