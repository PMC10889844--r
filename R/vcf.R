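#' Variant record container
#'
#' A `variant_set` is a column-oriented container for called variants:
#' one element per record, with per-sample genotype (`GT`) and allele-depth
#' (`AD`) strings kept verbatim until multi-allelic splitting. Record-level
#' evidence is the read depth (`DP`, supporting reads) and the RMS mapping
#' quality (`MQ`).
#'
#' @param chrom,pos,ref,alt Record columns; `alt` is the comma-joined ALT
#'   field (possibly multi-allelic).
#' @param dp,mq Numeric vectors (NA when the INFO key is absent).
#' @param gt,ad Character matrices, records x samples (`ad` may be NULL).
#' @param samples Sample names.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(chrom, pos, ref, alt, dp, mq, gt, ad = NULL, samples) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            length(dp) == n, length(mq) == n)
  if (n > 0L) {
    stopifnot(is.matrix(gt), nrow(gt) == n, ncol(gt) == length(samples))
    if (!is.null(ad)) stopifnot(nrow(ad) == n, ncol(ad) == length(samples))
    if (any(!nzchar(ref)) || any(!nzchar(alt)))
      stop("empty REF or ALT allele")
  }
  if (length(samples) == 0L) stop("a variant_set needs at least one sample")
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
         dp = as.numeric(dp), mq = as.numeric(mq),
         gt = gt, ad = ad, samples = as.character(samples)),
    class = "variant_set"
  )
}

#' Number of records in a variant_set
#' @param x A `variant_set`.
#' @return Integer count.
#' @export
n_variants <- function(x) length(x$pos)

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d record(s), %d sample(s): %s\n",
              n_variants(x), length(x$samples),
              paste(utils::head(x$samples, 8), collapse = ", ")))
  invisible(x)
}

subset_variants <- function(x, i) {
  variant_set(x$chrom[i], x$pos[i], x$ref[i], x$alt[i], x$dp[i], x$mq[i],
              x$gt[i, , drop = FALSE],
              if (!is.null(x$ad)) x$ad[i, , drop = FALSE] else NULL,
              x$samples)
}

#' Read a VCF file into a variant_set
#'
#' Supports the VCF v4.x subset used throughout: `INFO` keys `DP` and `MQ`,
#' `FORMAT` keys `GT` (required) and `AD` (optional). Genotypes stay
#' verbatim; use [split_multiallelic()] to obtain per-allele records with
#' classed genotype calls.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(v@gt) || ncol(v@gt) < 2L)
    stop("VCF format error: no sample columns in ", path)
  fmt <- v@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF format error: missing GT field in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  has_ad <- all(grepl("(^|:)AD(:|$)", fmt))
  ad <- if (has_ad) vcfR::extract.gt(v, element = "AD") else NULL
  dp <- suppressWarnings(vcfR::extract.info(v, element = "DP", as.numeric = TRUE))
  mq <- suppressWarnings(vcfR::extract.info(v, element = "MQ", as.numeric = TRUE))
  variant_set(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    dp = dp, mq = mq,
    gt = unname(gt),
    ad = if (!is.null(ad)) unname(ad) else NULL,
    samples = colnames(v@gt)[-1]
  )
}

#' Write a variant_set to a VCF v4.2 file
#'
#' Serialises records with `INFO` keys `DP`/`MQ` and `FORMAT` `GT:AD`
#' (plain `GT` when no allele depths are stored). Output is deterministic:
#' identical input yields byte-identical files.
#'
#' @param x A [variant_set()].
#' @param path Output path.
#' @param contig_lengths Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gojivar",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", x$samples), collapse = "\t"))
  if (n_variants(x) > 0L) {
    info <- sprintf("DP=%s;MQ=%s",
                    ifelse(is.na(x$dp), ".", format(x$dp, trim = TRUE, scientific = FALSE)),
                    ifelse(is.na(x$mq), ".", format(round(x$mq, 2), trim = TRUE,
                                                    scientific = FALSE)))
    if (!is.null(x$ad)) {
      cells <- matrix(paste(x$gt, ifelse(is.na(x$ad), ".", x$ad), sep = ":"),
                      nrow = n_variants(x))
      fmt <- "GT:AD"
    } else {
      cells <- x$gt
      fmt <- "GT"
    }
    cells[is.na(x$gt)] <- if (fmt == "GT") "./." else "./.:."
    body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", info, fmt,
                  sep = "\t")
    body <- paste(body, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a cohort assignment table
#'
#' Tab-separated file with columns `sample` and `cohort`; cohort labels
#' must be `cultivated` or `wild`.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: sample id -> cohort label.
#' @export
read_cohorts <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (nrow(df) == 0L) stop("cohort file is empty: ", path)
  cols <- tolower(names(df))
  s_col <- match(TRUE, cols %in% c("sample", "sample_id"))
  c_col <- match(TRUE, cols %in% c("cohort", "label"))
  if (is.na(s_col) || is.na(c_col))
    stop("cohort file must have 'sample' and 'cohort' columns: ", path)
  samples <- trimws(df[[s_col]]); labels <- trimws(df[[c_col]])
  if (anyDuplicated(samples))
    stop("duplicate sample id in cohort file: ",
         samples[duplicated(samples)][1])
  bad <- !labels %in% c("cultivated", "wild")
  if (any(bad))
    stop("unknown cohort label '", labels[bad][1],
         "' (expected 'cultivated' or 'wild')")
  stats::setNames(labels, samples)
}

#' Write a cohort assignment table
#' @param cohorts Named character vector (sample -> cohort).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohorts <- function(cohorts, path) {
  utils::write.table(
    data.frame(sample = names(cohorts), cohort = unname(cohorts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
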