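test_that("strand collapse is invariant over all 12 ordered substitutions", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seen <- character(0)
  for (r in bases) for (a in setdiff(bases, r)) {
    lab <- collapse_mutation_class(r, a)
    expect_true(lab %in% mutation_classes())
    expect_identical(lab, collapse_mutation_class(comp[[r]], comp[[a]]))
    seen <- c(seen, lab)
  }
  # every class is hit by exactly two ordered pairs
  expect_equal(unname(table(seen)[mutation_classes()]), rep(2L, 6),
               ignore_attr = TRUE)
  expect_identical(collapse_mutation_class("T", "C"), "T:A>C:G")
  expect_identical(collapse_mutation_class("A", "G"), "T:A>C:G")
  expect_identical(collapse_mutation_class("C", "G"), "C:G>G:C")
  expect_error(collapse_mutation_class("N", "A"), "ref and alt")
  expect_error(collapse_mutation_class("A", "A"), "identical")
})

test_that("ts/tv ratio and class partition follow directly from counts", {
  s <- snp_stream(c(rep("T", 600), rep("C", 300)),
                  c(rep("C", 600), rep("A", 300)))
  out <- spectrum_summary(s, callable_bases = 1000)
  expect_equal(out$snp_total, 900L)
  expect_equal(out$transitions, 600L)
  expect_equal(out$transversions, 300L)
  expect_equal(out$ts_tv_ratio, 2.0)
  expect_equal(sum(unlist(out[mutation_classes()])), out$snp_total)
})

test_that("a transition-only stream reports an absent ratio, no error", {
  s <- snp_stream(rep("T", 10), rep("C", 10))
  out <- spectrum_summary(s, callable_bases = 100)
  expect_true(is.na(out$ts_tv_ratio))
})

test_that("heterozygosity rate is per mille and scales with the denominator", {
  s <- snp_stream(rep("T", 8), rep("C", 8))
  s$gt_class <- cbind(c(rep("het", 5), "hom_alt", "hom_ref", "hom_alt"))
  s$samples <- "S1"
  out <- spectrum_summary(s, "S1", callable_bases = 1000)
  expect_equal(out$het_snp_count, 5L)
  expect_equal(out$het_rate_permille, 5.0)
  half <- spectrum_summary(s, "S1", callable_bases = 2000)
  expect_equal(half$het_rate_permille, out$het_rate_permille / 2)
})

test_that("InDel length percentages are proportions of all InDels", {
  idl <- list(ref = rep("A", 100), alt = rep("AT", 100),
              kind = rep(c("insertion", "deletion"), c(40, 60)),
              indel_length = rep(c(1L, 2L, 5L), c(50, 13, 37)))
  out <- indel_summary(idl, callable_bases = 1e4)
  expect_equal(out$insertion_count, 40)
  expect_equal(out$deletion_count, 60)
  expect_equal(out$length_percentages[["1"]], 50)
  expect_equal(out$length_percentages[["2"]], 13)
  expect_equal(sum(out$length_percentages), 100)
  expect_error(indel_summary(list(ref = "A", alt = "AT",
                                  kind = "insertion",
                                  indel_length = 51L),
                             callable_bases = 10), "outside")
})

test_that("windowed density bins by start position and conserves totals", {
  v <- list(chrom = c("c", "c", "c"), pos = c(1L, 2L, 15L))
  tr <- window_density(v, c(c = 20L), window_size = 10)
  expect_equal(tr$snp_count, c(2L, 1L))
  expect_equal(tr$start, c(0, 10))
  expect_equal(tr$end, c(10, 20))

  empty <- window_density(list(chrom = character(0), pos = integer(0)),
                          c(c = 25L), window_size = 10)
  expect_equal(empty$snp_count, c(0L, 0L, 0L))
  expect_equal(empty$end[3], 25)  # short terminal window

  expect_error(window_density(list(chrom = "c", pos = 30L), c(c = 20L), 10),
               "beyond chromosome length")
  expect_error(window_density(list(chrom = "x", pos = 1L), c(c = 20L), 10),
               "unknown chromosome")
})

test_that("simulated data recover configured spectrum parameters", {
  cfg <- simulation_config(seed = 202, chromosomes = c(c1 = 2e6),
                           n_cultivated = 1, n_wild = 0, n_genes = 0,
                           indel_rate = 0.002)
  sim <- simulate_genome(cfg)
  qc <- classify_variants(split_multiallelic(
    simulate_cohort_variants(cfg, sim$genome, sim$cds)))
  cb <- callable_bases(sim$genome)
  spec <- spectrum_summary(qc$kept, "Lb1", cb)

  target_tstv <- 1.72
  p <- target_tstv / (1 + target_tstv)
  se_ratio <- sqrt(p * (1 - p) / spec$snp_total) / (1 - p)^2
  expect_lt(abs(spec$ts_tv_ratio - target_tstv), 3 * se_ratio)

  se_het <- sqrt(cfg$het_rate_permille / 1000 * cb) / cb * 1000
  expect_lt(abs(spec$het_rate_permille - cfg$het_rate_permille), 3 * se_het)

  isum <- indel_summary(qc$kept, "Lb1", cb)
  p1 <- cfg$indel_length_probs[1]
  se_p1 <- 100 * sqrt(p1 * (1 - p1) / isum$indel_total)
  expect_lt(abs(isum$length_percentages[["1"]] - 100 * p1), 3 * se_p1)

  # the realised class ordering matches the configured spectrum
  counts <- unlist(spec[mutation_classes()])
  expect_identical(names(which.max(counts)), "C:G>T:A")
  expect_identical(names(which.min(counts)), "C:G>G:C")
})

test_that("terminal windows carry more variants under the end gradient", {
  cfg <- simulation_config(seed = 303, chromosomes = c(c1 = 2e6),
                           n_cultivated = 1, n_wild = 0, n_genes = 0,
                           end_gradient = 3)
  sim <- simulate_genome(cfg)
  qc <- classify_variants(split_multiallelic(
    simulate_cohort_variants(cfg, sim$genome, sim$cds)))
  tr <- window_density(qc$kept, genome_lengths(sim$genome),
                       window_size = 1e5)
  n <- nrow(tr)
  terminal <- c(1:2, (n - 1):n)                 # terminal 10% at each end
  central <- setdiff(seq_len(n), terminal)
  expect_gt(mean(tr$snp_count[terminal]), 1.5 * mean(tr$snp_count[central]))
  expect_equal(sum(tr$snp_count), sum(qc$kept$kind == "snp"))
})
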