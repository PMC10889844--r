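# Builders for tiny in-code fixtures shared across test files.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal VCF text with DP/MQ info and GT[:AD] cells
make_vcf <- function(rows, samples = c("S1", "S2"), format = "GT:AD") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"rms mq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  write_tmp(c(header, rows), ext = ".vcf")
}

vcf_row <- function(chrom, pos, ref, alt, dp, mq, cells,
                    format = "GT:AD") {
  parts <- c(if (!is.na(dp)) paste0("DP=", dp),
             if (!is.na(mq)) paste0("MQ=", mq))
  info <- if (length(parts)) paste(parts, collapse = ";") else "."
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, format, cells),
        collapse = "\t")
}

# biallelic classified variant table for spectrum tests, no genotypes
snp_stream <- function(ref, alt) {
  list(ref = ref, alt = alt, kind = rep("snp", length(ref)),
       chrom = rep("c", length(ref)), pos = seq_along(ref))
}

tiny_cohorts <- function(states) {
  # states: named character vector of sample -> cohort
  states
}
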