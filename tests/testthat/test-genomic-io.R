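test_that("FASTA reading normalises case, keeps order and round-trips", {
  p <- write_tmp(c(">chr1 first", "ACGT", ">chr2", "acgtn"), ".fa")
  g <- read_fasta(p)
  expect_identical(names(g), c("chr1", "chr2"))
  expect_identical(unname(g[1]), "ACGT")
  expect_identical(unname(g[2]), "ACGTN")  # lowercase uppercased
  expect_identical(unname(genome_lengths(g)), c(4L, 5L))

  out <- tempfile(fileext = ".fa")
  write_fasta(g, out)
  expect_identical(read_fasta(out), g)
})

test_that("malformed FASTA errors name the offending line", {
  p <- write_tmp(c(">chr1", "ACGT", "ACQT"), ".fa")
  expect_error(read_fasta(p), "line 3")
  p2 <- write_tmp(c("ACGT"), ".fa")
  expect_error(read_fasta(p2), "line 1")
  p3 <- write_tmp(c(">chr1", "AC", ">chr1", "GG"), ".fa")
  expect_error(read_fasta(p3), "duplicate")
})

test_that("callable_bases excludes Ns only on request", {
  g <- c(a = "ACGTN", b = "NNAA")
  expect_equal(callable_bases(g), 6)
  expect_equal(callable_bases(g, exclude_n = FALSE), 9)
})

test_that("GFF3 CDS models round-trip and validate frame", {
  m1 <- cds_model("GENEA", "chr1", "+", rbind(c(101, 106), c(201, 203)))
  m2 <- cds_model("GENEB", "chr1", "-", rbind(c(501, 530)))
  expect_equal(m1$cds_length, 9L)
  p <- tempfile(fileext = ".gff3")
  write_cds_gff3(list(m1, m2), p)
  back <- read_cds_annotation(p)
  expect_setequal(names(back), c("GENEA", "GENEB"))
  expect_equal(back$GENEA$segments, m1$segments, ignore_attr = TRUE)
  expect_identical(back$GENEB$strand, "-")

  expect_error(cds_model("BAD", "chr1", "+", rbind(c(1, 10))),
               "BAD.*not divisible by 3")
  expect_error(cds_model("OVL", "chr1", "+", rbind(c(1, 6), c(4, 9))),
               "overlap")
})

test_that("VCF parsing maps GT and AD fields as specified", {
  p <- make_vcf(c(
    vcf_row("chr1", 100, "A", "G", 30, 50, c("0/1:31,69", "1/1:0,40")),
    vcf_row("chr1", 200, "C", "T,TG", 25, 44, c("0/1:10,5,5", "2/2:1,0,20")),
    vcf_row("chr1", 300, "G", "A", 12, 33, c("./.:.", "0/0:12,0"))))
  vs <- read_vcf(p)
  expect_s3_class(vs, "variant_set")
  expect_equal(n_variants(vs), 3L)
  expect_identical(vs$samples, c("S1", "S2"))
  expect_equal(vs$dp, c(30, 25, 12))

  bi <- split_multiallelic(vs)
  # two ALT alleles become two records: 3 -> 4
  expect_equal(n_variants(bi), 4L)
  expect_identical(bi$gt_class[1, ], c("het", "hom_alt"))
  expect_equal(bi$alt_frac[1, 1], 69)          # AD=31,69 -> 69%
  expect_equal(bi$alt_frac[1, 2], 100)
  # sample genotyped 2/2 is missing on the first split record,
  # hom_alt on the second
  expect_identical(bi$gt_class[2, 2], "missing")
  expect_identical(bi$gt_class[3, 2], "hom_alt")
  expect_identical(bi$gt_class[4, ], c("missing", "hom_ref"))
})

test_that("a biallelic record passes through splitting unchanged", {
  p <- make_vcf(vcf_row("chr1", 5, "A", "T", 9, 31, c("0/1:4,5", "0/0:9,0")))
  bi <- split_multiallelic(read_vcf(p))
  expect_equal(n_variants(bi), 1L)
  expect_identical(bi$alt, "T")
})

test_that("VCF without AD marks het fractions unavailable", {
  p <- make_vcf(vcf_row("chr1", 5, "A", "T", 9, 31, c("0/1", "1/1")),
                format = "GT")
  bi <- split_multiallelic(read_vcf(p))
  expect_true(is.na(bi$alt_frac[1, 1]))
  expect_equal(bi$alt_frac[1, 2], 100)  # hom-alt is 100 by definition
})

test_that("VCF without GT is a format error", {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1"), collapse = "\t"),
             paste(c("chr1", "1", ".", "A", "G", ".", ".", ".", "AD",
                     "3,4"), collapse = "\t"))
  expect_error(read_vcf(write_tmp(lines, ".vcf")), "GT")
})

test_that("VCF writing round-trips field-for-field", {
  p <- make_vcf(c(
    vcf_row("chr1", 100, "A", "G", 30, 50.25, c("0/1:31,69", "1/1:0,40")),
    vcf_row("chr2", 7, "CT", "C", 11, 29, c("0/0:11,0", "0/1:6,5"))))
  vs <- read_vcf(p)
  out <- tempfile(fileext = ".vcf")
  write_vcf(vs, out)
  back <- read_vcf(out)
  for (f in c("chrom", "pos", "ref", "alt", "dp", "mq", "gt", "ad", "samples"))
    expect_equal(back[[f]], vs[[f]], info = f)
})

test_that("cohort table parsing enforces labels and uniqueness", {
  p <- system.file("extdata", "cohorts.tsv", package = "gojivar")
  coh <- read_cohorts(p)
  expect_length(coh, 8L)
  expect_equal(sum(coh == "cultivated"), 5L)
  expect_equal(sum(coh == "wild"), 3L)
  expect_identical(names(coh)[6], "Lb6w")

  expect_error(read_cohorts(write_tmp("sample\tcohort", ".tsv")), "empty")
  expect_error(read_cohorts(write_tmp(
    c("sample\tcohort", "Lb1\tcultivated", "Lb1\twild"), ".tsv")),
    "duplicate")
  expect_error(read_cohorts(write_tmp(
    c("sample\tcohort", "Lb1\tdomestic"), ".tsv")), "unknown cohort")
})
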