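small_cfg <- function(...) {
  simulation_config(seed = 99, chromosomes = c(s1 = 5e4, s2 = 5e4),
                    n_genes = 2L, gene_length = 300L,
                    coding_snps_per_gene = 8L, ...)
}

test_that("a fixed seed reproduces every output byte-for-byte", {
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  simulate_run(small_cfg(), d1)
  simulate_run(small_cfg(), d2)
  for (f in c("genome.fa", "genes.gff3", "variants.vcf", "cohorts.tsv",
              "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("simulated outputs round-trip through the readers", {
  d <- file.path(tempdir(), "runC")
  sim <- simulate_run(small_cfg(), d)
  genome <- read_fasta(sim$paths$fasta)
  expect_identical(genome, sim$genome)
  cds <- read_cds_annotation(sim$paths$gff)
  expect_setequal(names(cds), names(sim$cds))
  for (g in names(cds))
    expect_equal(cds[[g]]$segments, sim$cds[[g]]$segments,
                 ignore_attr = TRUE)
  vs <- read_vcf(sim$paths$vcf)
  expect_equal(n_variants(vs), n_variants(sim$variants))
  expect_identical(vs$gt, sim$variants$gt)
  expect_equal(vs$pos, sim$variants$pos)
  coh <- read_cohorts(sim$paths$cohorts)
  expect_identical(coh, small_cfg()$cohorts)
})

test_that("gene placement avoids overlap and stays in frame", {
  cfg <- simulation_config(seed = 3, chromosomes = c(s1 = 2e4),
                           n_genes = 6L, gene_length = 600L)
  sim <- simulate_genome(cfg)
  segs <- do.call(rbind, lapply(sim$cds, function(m)
    cbind(m$segments, gene = match(m$gene_id, names(sim$cds)))))
  spans <- do.call(rbind, lapply(sim$cds, function(m)
    c(min(m$segments[, "start"]), max(m$segments[, "end"]))))
  ord <- order(spans[, 1])
  expect_true(all(spans[ord, 1][-1] > spans[ord, 2][-nrow(spans)]))
  for (m in sim$cds) expect_equal(m$cds_length %% 3L, 0L)
})

test_that("the configured filter pass rate is recovered", {
  cfg <- simulation_config(seed = 17, chromosomes = c(s1 = 1e6),
                           n_cultivated = 1, n_wild = 0, n_genes = 0)
  sim <- simulate_genome(cfg)
  vs <- simulate_cohort_variants(cfg, sim$genome, sim$cds)
  qc <- classify_variants(split_multiallelic(vs))
  pass <- n_variants(qc$kept) / n_variants(vs)
  se <- sqrt(0.95 * 0.05 / n_variants(vs))
  expect_lt(abs(pass - cfg$filter_pass_rate), 3 * se)
  # dropped records carry evidence-based reasons
  expect_setequal(unique(qc$dropped$reason),
                  c("supporting reads not above threshold",
                    "mapping quality not above threshold"))
})

test_that("an all-discriminating configuration is recovered exactly", {
  cfg <- simulation_config(seed = 23, chromosomes = c(s1 = 1e5),
                           snp_rate = 1e-4, het_rate_permille = 0.05,
                           indel_rate = 0,
                           n_genes = 2L, gene_length = 300L,
                           coding_snps_per_gene = 10L,
                           discriminating_fraction = 1,
                           filter_pass_rate = 1)
  sim <- simulate_genome(cfg)
  vs <- simulate_cohort_variants(cfg, sim$genome, sim$cds)
  qc <- classify_variants(split_multiallelic(vs))
  for (m in sim$cds) {
    sm <- site_matrix_from_variants(qc$kept, m, sim$genome)
    rep <- gene_discrimination_report(sm, cfg$cohorts)
    expect_equal(rep$n_discriminating, rep$n_sites)
    expect_equal(rep$percent_discriminating, 100L)
  }
})

test_that("the planted discriminating fraction is recovered within noise", {
  cfg <- simulation_config(seed = 31, chromosomes = c(s1 = 2e6),
                           snp_rate = 1e-6, het_rate_permille = 5e-4,
                           indel_rate = 0,
                           n_genes = 20L, gene_length = 900L,
                           coding_snps_per_gene = 10L,
                           discriminating_fraction = 0.55)
  sim <- simulate_genome(cfg)
  vs <- simulate_cohort_variants(cfg, sim$genome, sim$cds)
  truth <- attr(vs, "truth")$coding_sites
  qc <- classify_variants(split_multiallelic(vs))
  n_disc <- 0L; n_tot <- 0L
  for (m in sim$cds) {
    sm <- site_matrix_from_variants(qc$kept, m, sim$genome)
    rep <- gene_discrimination_report(sm, cfg$cohorts)
    n_disc <- n_disc + rep$n_discriminating
    n_tot <- n_tot + rep$n_sites
  }
  est <- n_disc / n_tot
  se <- sqrt(0.55 * 0.45 / n_tot)
  expect_lt(abs(est - 0.55), 3 * se)
  # the pipeline verdicts agree with the generator's ground truth
  kept_key <- paste(qc$kept$chrom, qc$kept$pos)
  planted_kept <- truth[paste(truth$chrom, truth$pos) %in% kept_key, ]
  expect_equal(n_tot, nrow(planted_kept))
  expect_equal(n_disc, sum(planted_kept$discriminating))
})

test_that("invalid configurations fail fast", {
  expect_error(simulation_config(class_probs = rep(0.2, 6)), "sum to 1")
  expect_error(simulation_config(gene_length = 100L))
  expect_error(simulation_config(snp_rate = 1e-4,
                                 het_rate_permille = 5.037),
               "exceeds 1")
  expect_error(simulate_genome(
    simulation_config(chromosomes = c(s1 = 1e3), n_genes = 2L,
                      gene_length = 900L, snp_rate = 0.02)),
    "config error")
})
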