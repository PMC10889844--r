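#!/usr/bin/env Rscript
# Profile the simulated cohort: post-call filtering, per-sample mutation
# spectra with ts/tv and heterozygosity, InDel length law, and windowed
# density tracks. Reads results/simulated_study/, writes results/profile/.

suppressPackageStartupMessages(library(gojivar))

run_dir <- file.path("results", "simulated_study")
out_dir <- file.path("results", "profile")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta(file.path(run_dir, "genome.fa"))
qc <- qc_vcf(file.path(run_dir, "variants.vcf"),
             report_path = file.path(out_dir, "filter_report.tsv"))
message(sprintf("kept %d of %d records after depth/mapping-quality filters",
                n_variants(qc$kept), n_variants(qc$kept) + nrow(qc$dropped)))

cb <- callable_bases(genome)
spec <- spectrum_table(qc$kept, cb)
write.table(spec, file.path(out_dir, "spectrum.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("mean ts/tv %.3f; het rate range %.3f-%.3f permille",
                mean(spec$ts_tv_ratio), min(spec$het_rate_permille),
                max(spec$het_rate_permille)))

indels <- do.call(rbind, lapply(spec$sample_id, function(s) {
  i <- indel_summary(qc$kept, s, cb)
  data.frame(sample_id = s, insertions = i$insertion_count,
             deletions = i$deletion_count,
             pct_1bp = round(i$length_percentages[["1"]], 2),
             pct_2bp = round(i$length_percentages[["2"]], 2),
             pct_3bp = round(i$length_percentages[["3"]], 2))
}))
write.table(indels, file.path(out_dir, "indel_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("1-bp InDel share across samples: %.1f%%-%.1f%%",
                min(indels$pct_1bp), max(indels$pct_1bp)))

dens <- window_density(qc$kept, genome_lengths(genome), window_size = 1e5)
write.table(dens, file.path(out_dir, "density.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ratio <- attr(dens, "snp_indel_ratio")
message(sprintf("SNP:InDel ratio per chromosome: %s",
                paste(sprintf("%s=%.1f", names(ratio), ratio),
                      collapse = ", ")))
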