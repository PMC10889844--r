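#' Post-call filter thresholds
#'
#' Thresholds mirror the mpileup post-call filtering used upstream of this
#' analysis: a variant is kept only when it is supported by *over*
#' `min_supporting_reads` reads and its RMS mapping quality *exceeds*
#' `min_rms_mapping_quality` — both comparisons are strict. InDels longer
#' than `max_indel_length` bases are rejected outright.
#'
#' @param min_supporting_reads Exclusive lower bound on supporting reads
#'   (record-level DP). Default 4.
#' @param min_rms_mapping_quality Exclusive lower bound on RMS mapping
#'   quality (record-level MQ). Default 20.
#' @param max_indel_length Maximum InDel length in bases. Default 50.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_supporting_reads = 4,
                              min_rms_mapping_quality = 20,
                              max_indel_length = 50) {
  stopifnot(min_supporting_reads > 0, min_rms_mapping_quality > 0,
            max_indel_length > 0)
  structure(list(min_supporting_reads = min_supporting_reads,
                 min_rms_mapping_quality = min_rms_mapping_quality,
                 max_indel_length = max_indel_length),
            class = "filter_thresholds")
}

# genotype class codes used throughout
.GT_CLASSES <- c("hom_ref", "hom_alt", "het", "missing")

#' Split multi-allelic records into per-allele records
#'
#' Each record with k ALT alleles becomes k biallelic records. Per-sample
#' genotypes are recoded against the split allele: `0/0` -> `hom_ref`,
#' `k/k` -> `hom_alt`, `0/k` (either order) -> `het`, `./.` -> `missing`;
#' a genotype carrying any *other* alternate allele becomes `missing` for
#' that split record. Heterozygous alt-read fractions are computed from AD
#' (ref depth vs this allele's depth) when available, else left `NA`.
#'
#' @param x A [variant_set()] as returned by [read_vcf()].
#' @return A `biallelic_variants` object: like a `variant_set` but with a
#'   single `alt` allele per record, a `gt_class` character matrix and an
#'   `alt_frac` numeric matrix (percent, 0-100) in place of raw GT/AD.
#' @export
split_multiallelic <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  if (inherits(x, "biallelic_variants")) return(x)  # idempotent
  alts <- strsplit(x$alt, ",", fixed = TRUE)
  nalt <- lengths(alts)
  row_i <- rep(seq_along(nalt), nalt)
  allele <- unlist(lapply(nalt, seq_len), use.names = FALSE)
  n <- length(row_i)
  s <- length(x$samples)

  gt_raw <- x$gt[row_i, , drop = FALSE]
  a1 <- sub("^([0-9.]+)[/|].*$", "\\1", gt_raw)
  a2 <- sub("^[0-9.]+[/|]([0-9.]+)$", "\\1", gt_raw)
  # haploid or malformed cells fall back to missing
  ok <- grepl("^[0-9.]+[/|][0-9.]+$", gt_raw)
  k <- matrix(as.character(allele), nrow = n, ncol = s)
  gt_class <- matrix("missing", nrow = n, ncol = s)
  hom_ref <- ok & a1 == "0" & a2 == "0"
  hom_alt <- ok & a1 == k & a2 == k
  het <- ok & ((a1 == "0" & a2 == k) | (a1 == k & a2 == "0"))
  gt_class[hom_ref] <- "hom_ref"
  gt_class[hom_alt] <- "hom_alt"
  gt_class[het] <- "het"

  alt_frac <- matrix(NA_real_, nrow = n, ncol = s)
  alt_frac[hom_ref] <- 0
  alt_frac[hom_alt] <- 100
  if (!is.null(x$ad)) {
    ad_raw <- x$ad[row_i, , drop = FALSE]
    idx <- which(het & !is.na(ad_raw) & ad_raw != ".")
    if (length(idx)) {
      parts <- strsplit(ad_raw[idx], ",", fixed = TRUE)
      al <- allele[(idx - 1L) %% n + 1L]
      frac <- vapply(seq_along(idx), function(j) {
        p <- suppressWarnings(as.numeric(parts[[j]]))
        if (length(p) <= al[j] || anyNA(p[c(1L, al[j] + 1L)])) return(NA_real_)
        tot <- p[1L] + p[al[j] + 1L]
        if (tot <= 0) NA_real_ else 100 * p[al[j] + 1L] / tot
      }, numeric(1))
      alt_frac[idx] <- frac
    }
  }

  out <- variant_set(x$chrom[row_i], x$pos[row_i], x$ref[row_i],
                     vapply(seq_len(n), function(j) alts[[row_i[j]]][allele[j]],
                            character(1)),
                     x$dp[row_i], x$mq[row_i],
                     gt = gt_class, ad = NULL, samples = x$samples)
  out$gt_class <- gt_class
  out$alt_frac <- alt_frac
  out$gt <- gt_class
  class(out) <- c("biallelic_variants", "variant_set")
  out
}

subset_biallelic <- function(x, i) {
  out <- variant_set(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                     x$dp[i], x$mq[i],
                     gt = x$gt_class[i, , drop = FALSE], ad = NULL,
                     samples = x$samples)
  out$gt_class <- x$gt_class[i, , drop = FALSE]
  out$alt_frac <- x$alt_frac[i, , drop = FALSE]
  if (!is.null(x$kind)) {
    out$kind <- x$kind[i]
    out$indel_length <- x$indel_length[i]
  }
  class(out) <- class(x)
  out
}

#' Classify biallelic variants and apply post-call filters
#'
#' Partitions the input into kept SNPs, kept insertions, kept deletions and
#' dropped records (each with a reason), applying the strict read-support
#' and mapping-quality thresholds. Multi-nucleotide substitutions (REF and
#' ALT of equal length > 1) are decomposed into per-base SNPs at the
#' offsets where the alleles differ. Records with symbolic/breakend
#' alleles are rejected as unsupported.
#'
#' @param x A `biallelic_variants` object from [split_multiallelic()].
#' @param thresholds A [filter_thresholds()].
#' @return List with `kept` (a `classified_variants` object carrying
#'   `kind` in `{snp, insertion, deletion}` and `indel_length`) and
#'   `dropped` (data.frame `chrom`, `pos`, `ref`, `alt`, `reason`).
#' @export
classify_variants <- function(x, thresholds = filter_thresholds()) {
  stopifnot(inherits(x, "biallelic_variants"))
  n <- n_variants(x)
  reason <- rep(NA_character_, n)

  symbolic <- grepl("[^ACGT]", x$ref) | grepl("[^ACGT]", x$alt)
  reason[symbolic] <- "unsupported allele"

  rl <- nchar(x$ref); al <- nchar(x$alt)
  kind <- rep(NA_character_, n)
  kind[!symbolic & rl == 1L & al == 1L & x$ref != x$alt] <- "snp"
  kind[!symbolic & al > rl] <- "insertion"
  kind[!symbolic & al < rl] <- "deletion"
  mnp <- !symbolic & rl == al & rl > 1L
  ilen <- abs(al - rl)
  too_long <- !symbolic & kind %in% c("insertion", "deletion") &
    ilen > thresholds$max_indel_length
  reason[too_long] <- sprintf("indel length %d > %d", ilen[too_long],
                              thresholds$max_indel_length)
  ident <- !symbolic & !mnp & is.na(kind) & is.na(reason)
  reason[ident] <- "ref equals alt"

  # decompose MNPs into per-base SNPs at differing offsets
  extra <- NULL
  if (any(mnp)) {
    pieces <- lapply(which(mnp), function(i) {
      rb <- strsplit(x$ref[i], "", fixed = TRUE)[[1]]
      ab <- strsplit(x$alt[i], "", fixed = TRUE)[[1]]
      off <- which(rb != ab)
      if (length(off) == 0L) return(NULL)
      list(i = i, pos = x$pos[i] + off - 1L, ref = rb[off], alt = ab[off])
    })
    pieces <- Filter(Negate(is.null), pieces)
    if (length(pieces)) {
      src <- unlist(lapply(pieces, function(p) rep(p$i, length(p$pos))))
      extra <- variant_set(
        x$chrom[src],
        unlist(lapply(pieces, `[[`, "pos")),
        unlist(lapply(pieces, `[[`, "ref")),
        unlist(lapply(pieces, `[[`, "alt")),
        x$dp[src], x$mq[src],
        gt = x$gt_class[src, , drop = FALSE], ad = NULL,
        samples = x$samples)
      extra$gt_class <- x$gt_class[src, , drop = FALSE]
      extra$alt_frac <- x$alt_frac[src, , drop = FALSE]
      extra$kind <- rep("snp", n_variants(extra))
      extra$indel_length <- rep(0L, n_variants(extra))
      class(extra) <- c("classified_variants", "biallelic_variants",
                        "variant_set")
    }
  }

  keepable <- is.na(reason) & !mnp & !is.na(kind)
  # evidence filters: strict inequalities ("over four", "exceeding 20")
  no_evidence <- keepable & (is.na(x$dp) | is.na(x$mq))
  reason[no_evidence] <- "missing evidence"
  low_dp <- keepable & !no_evidence & x$dp <= thresholds$min_supporting_reads
  reason[low_dp] <- "supporting reads not above threshold"
  low_mq <- keepable & !no_evidence & !low_dp &
    x$mq <= thresholds$min_rms_mapping_quality
  reason[low_mq] <- "mapping quality not above threshold"

  keep <- keepable & is.na(reason)
  kept <- subset_biallelic(x, which(keep))
  kept$kind <- kind[keep]
  kept$indel_length <- ifelse(kept$kind == "snp", 0L, ilen[keep])
  class(kept) <- c("classified_variants", "biallelic_variants", "variant_set")

  if (!is.null(extra)) {
    # MNP-derived SNPs face the same evidence filters as their source record
    edp <- extra$dp; emq <- extra$mq
    e_keep <- !is.na(edp) & !is.na(emq) &
      edp > thresholds$min_supporting_reads &
      emq > thresholds$min_rms_mapping_quality
    kept <- .bind_classified(kept, subset_biallelic(extra, which(e_keep)))
    mnp_missing <- which(mnp)[is.na(x$dp[mnp]) | is.na(x$mq[mnp])]
    reason[mnp_missing] <- "missing evidence"
    mnp_low <- setdiff(which(mnp), mnp_missing)
    mnp_low <- mnp_low[x$dp[mnp_low] <= thresholds$min_supporting_reads |
                         x$mq[mnp_low] <= thresholds$min_rms_mapping_quality]
    reason[mnp_low] <- "evidence below threshold"
  }

  dropped <- data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref,
                        alt = x$alt, reason = reason,
                        stringsAsFactors = FALSE)[!is.na(reason), , drop = FALSE]
  rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

.bind_classified <- function(a, b) {
  if (n_variants(b) == 0L) return(a)
  if (n_variants(a) == 0L) return(b)
  out <- variant_set(c(a$chrom, b$chrom), c(a$pos, b$pos), c(a$ref, b$ref),
                     c(a$alt, b$alt), c(a$dp, b$dp), c(a$mq, b$mq),
                     gt = rbind(a$gt_class, b$gt_class), ad = NULL,
                     samples = a$samples)
  out$gt_class <- rbind(a$gt_class, b$gt_class)
  out$alt_frac <- rbind(a$alt_frac, b$alt_frac)
  out$kind <- c(a$kind, b$kind)
  out$indel_length <- c(a$indel_length, b$indel_length)
  class(out) <- class(a)
  out
}

#' One-call QC: read, split, classify and filter a VCF
#'
#' @param path VCF path.
#' @param thresholds A [filter_thresholds()].
#' @param report_path Optional path for a tab-separated drop report
#'   (record key and reason).
#' @return As [classify_variants()].
#' @export
qc_vcf <- function(path, thresholds = filter_thresholds(),
                   report_path = NULL) {
  res <- classify_variants(split_multiallelic(read_vcf(path)), thresholds)
  if (!is.null(report_path))
    utils::write.table(res$dropped, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
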