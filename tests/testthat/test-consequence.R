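test_that("the packaged genetic code matches the Biostrings reference", {
  codons <- names(codon_table())
  ref <- Biostrings::GENETIC_CODE[codons]
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
           "*" = "Stop")
  expect_identical(unname(codon_table()), unname(aa3[ref]))
  expect_length(codon_table(), 64L)
})

test_that("amino-acid properties partition the 20 standard residues", {
  props <- amino_acid_properties()
  expect_length(props, 20L)
  expect_setequal(unique(props), c("nonpolar", "polar", "basic", "acidic"))
  expect_false(anyDuplicated(names(props)) > 0)
})

test_that("genomic-to-CDS projection handles splicing and strand", {
  plus1 <- cds_model("G1", "c", "+", rbind(c(101, 130)))
  expect_equal(project_to_cds(plus1, 101L)$cds_position, 1L)
  expect_equal(project_to_cds(plus1, 103L)$offset_in_codon, 3L)

  spliced <- cds_model("G2", "c", "+", rbind(c(101, 106), c(201, 203)))
  expect_equal(project_to_cds(spliced, 201L)$cds_position, 7L)
  expect_true(is.na(project_to_cds(spliced, 150L)$cds_position))  # intron

  minus <- cds_model("G3", "c", "-", rbind(c(101, 130)))
  pr <- project_to_cds(minus, c(130L, 101L))
  expect_equal(pr$cds_position, c(1L, 30L))
  expect_equal(pr$codon_index, c(1L, 10L))
})

test_that("SNPs sharing a codon form one group", {
  g <- group_codon_variants(c(287L, 288L))
  expect_length(g, 1L)
  expect_identical(names(g), "96")
  g2 <- group_codon_variants(c(100L, 104L))
  expect_length(g2, 2L)
})

test_that("codon assembly reproduces the published worked examples", {
  # Lys -> Arg via two substitutions in one codon (AAA -> CGA)
  seq1 <- paste(c(rep("GGG", 95), "AAA"), collapse = "")
  ch <- build_codon_change("g", c(286L, 287L), list("C", "G"), seq1)
  expect_identical(ch$alt_codons, "CGA")
  expect_identical(ch$ref_aa, "Lys")
  expect_identical(ch$alt_aas, "Arg")
  expect_identical(ch$effect, "missense")
  expect_false(ch$charge_change)  # basic -> basic

  # Lys -> Asp (AAA -> GAC; the middle base is unchanged)
  ch2 <- build_codon_change("g", c(286L, 288L), list("G", "C"), seq1)
  expect_identical(ch2$alt_codons, "GAC")
  expect_identical(ch2$alt_aas, "Asp")
  expect_true(ch2$charge_change)  # basic -> acidic

  # TCT with attested combinations GCT, TCA, TCG -> Ser/Ala/Ser/Ser
  seq3 <- "TCT"
  sample_alleles <- cbind(c(1L, 0L), c(0L, 1L), c(0L, 2L), c(0L, 0L))
  ch3 <- build_codon_change("g", c(1L, 3L), list("G", c("A", "G")), seq3,
                            sample_alleles = sample_alleles)
  expect_setequal(ch3$alt_codons, c("GCT", "TCA", "TCG"))
  expect_identical(ch3$ref_aa, "Ser")
  expect_setequal(ch3$alt_aas, c("Ala", "Ser"))
  expect_identical(ch3$effect, "missense")   # one combination is Ala
  expect_true(ch3$polarity_change)           # Ser (polar) -> Ala (nonpolar)

  # full enumeration would add the doubly-substituted codons
  ch4 <- build_codon_change("g", c(1L, 3L), list("G", c("A", "G")), seq3,
                            full_enumeration = TRUE)
  expect_setequal(ch4$alt_codons, c("GCT", "TCA", "TCG", "GCA", "GCG"))
})

test_that("an allele clashing with the reference base is an error", {
  expect_error(build_codon_change("g", 1L, list("A"), "AAA"),
               "equals reference")
})

test_that("effect classification agrees with brute-force translation", {
  # oracle: Biostrings translation over all 64 codons x 9 substitutions
  bases <- c("A", "C", "G", "T")
  codons <- names(codon_table())
  n_checked <- 0L
  for (codon in codons) {
    for (off in 1:3) for (b in setdiff(bases, substr(codon, off, off))) {
      alt <- codon
      substr(alt, off, off) <- b
      ch <- classify_effect(list(ref_codon = codon, alt_codons = alt))
      oracle_ref <- as.character(Biostrings::translate(
        Biostrings::DNAString(codon), no.init.codon = TRUE))
      oracle_alt <- as.character(Biostrings::translate(
        Biostrings::DNAString(alt), no.init.codon = TRUE))
      if (oracle_ref != "*" && oracle_alt == "*") {
        expect_identical(ch$effect, "nonsense")
      } else if (oracle_ref == "*" && oracle_alt != "*") {
        expect_identical(ch$effect, "stop_loss")
      } else if (oracle_ref == oracle_alt) {
        expect_identical(ch$effect, "synonymous")
      } else {
        expect_identical(ch$effect, "missense")
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 576L)
})

test_that("property flags fire only on the documented crossings", {
  syn <- classify_effect(list(ref_codon = "TTA", alt_codons = "CTA"))
  expect_identical(syn$effect, "synonymous")
  expect_false(syn$polarity_change)
  expect_false(syn$charge_change)

  chg <- classify_effect(list(ref_codon = "AAA", alt_codons = "GAA"))
  expect_identical(chg$alt_aas, "Glu")
  expect_true(chg$charge_change)    # Lys (basic) -> Glu (acidic)
  expect_false(chg$polarity_change) # charged classes, not polar<->nonpolar

  pol <- classify_effect(list(ref_codon = "TCT", alt_codons = "GCT"))
  expect_true(pol$polarity_change)
  expect_false(pol$charge_change)

  unk <- classify_effect(list(ref_codon = "ANA", alt_codons = "AAA"))
  expect_identical(unk$effect, "unknown")
})

test_that("gene consequences complement alleles on minus-strand genes", {
  # genome: CDS on minus strand at 11..19; mRNA = revcomp(genomic 11..19)
  genomic_cds <- "CATTTTGGC"
  genome <- c(c1 = paste0("AAAAAAAAAA", genomic_cds, "AA"))
  cds <- cds_model("GM", "c1", "-", rbind(c(11, 19)))
  expect_identical(cds_sequence(cds, genome), "GCCAAAATG")
  # genomic SNP T->C at position 15 is A->G at CDS position 5 (codon 2 AAA)
  p <- make_vcf(vcf_row("c1", 15, "T", "C", 30, 50,
                        c("0/1:10,10", "0/0:20,0")))
  qc <- classify_variants(split_multiallelic(read_vcf(p)))
  gc <- gene_consequences(qc$kept, cds, genome)
  expect_equal(nrow(gc$sites), 1L)
  expect_equal(gc$sites$cds_position, 5L)
  expect_identical(gc$sites$ref, "A")
  expect_identical(gc$sites$alt, "G")
  expect_identical(gc$changes[[1]]$ref_codon, "AAA")
  expect_identical(gc$changes[[1]]$alt_codons, "AGA")
  expect_identical(gc$changes[[1]]$effect, "missense")
})

test_that("non-coding SNPs are tallied, not errors", {
  genome <- c(c1 = paste(rep("A", 30), collapse = ""))
  cds <- cds_model("GP", "c1", "+", rbind(c(10, 18)))
  p <- make_vcf(c(vcf_row("c1", 2, "A", "G", 30, 50, c("0/1:9,9", "0/0:9,0")),
                  vcf_row("c1", 12, "A", "G", 30, 50, c("0/1:9,9", "0/0:9,0"))))
  qc <- classify_variants(split_multiallelic(read_vcf(p)))
  gc <- gene_consequences(qc$kept, cds, genome)
  expect_equal(gc$n_noncoding, 1L)
  expect_equal(nrow(gc$sites), 1L)
})
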