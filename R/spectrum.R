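#' The six strand-collapsed mutation classes
#'
#' A substitution and its reverse complement are the same event read from
#' opposite strands (a T-to-C change on one strand is an A-to-G change at
#' the same position on the other), so the 12 ordered base substitutions
#' collapse to six classes.
#'
#' @return Character vector of the six class labels.
#' @export
mutation_classes <- function() {
  c("T:A>C:G", "T:A>G:C", "C:G>T:A", "C:G>A:T", "T:A>A:T", "C:G>G:C")
}

.CLASS_LOOKUP <- c(
  "T>C" = "T:A>C:G", "A>G" = "T:A>C:G",
  "T>G" = "T:A>G:C", "A>C" = "T:A>G:C",
  "T>A" = "T:A>A:T", "A>T" = "T:A>A:T",
  "C>T" = "C:G>T:A", "G>A" = "C:G>T:A",
  "C>A" = "C:G>A:T", "G>T" = "C:G>A:T",
  "C>G" = "C:G>G:C", "G>C" = "C:G>G:C"
)

# classes counted as transitions (purine<->purine / pyrimidine<->pyrimidine)
.TS_CLASSES <- c("T:A>C:G", "C:G>T:A")

#' Collapse a substitution to its strand-symmetric mutation class
#'
#' @param ref,alt Single-base reference and alternate alleles (vectors).
#' @return Character vector of class labels; complementing both bases
#'   yields the same label.
#' @export
#' @examples
#' collapse_mutation_class("T", "C")  # same class as A>G
collapse_mutation_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T")))
    stop("mutation class requires ref and alt in {A,C,G,T}")
  if (any(ref == alt))
    stop("mutation class undefined for identical ref and alt")
  unname(.CLASS_LOOKUP[paste0(ref, ">", alt)])
}

.carried_mask <- function(snps, sample_id) {
  if (is.null(sample_id) || is.null(snps$gt_class)) {
    rep(TRUE, length(snps$ref))
  } else {
    j <- match(sample_id, snps$samples)
    if (is.na(j)) stop("unknown sample: ", sample_id)
    snps$gt_class[, j] %in% c("het", "hom_alt")
  }
}

#' Per-sample SNP spectrum summary
#'
#' Counts kept SNPs carried by one sample (heterozygous or homozygous
#' alternate) per strand-collapsed class, and derives the
#' transition/transversion ratio and the per-mille heterozygosity rate
#' (heterozygous SNP calls per thousand callable bases).
#'
#' @param snps Kept SNPs: a `classified_variants` object (rows of other
#'   kinds are ignored), or any list with `ref`/`alt` single-base columns
#'   (then all records are counted and `sample_id` may be `NULL`).
#' @param sample_id Sample to summarise, or `NULL` to count every record.
#' @param callable_bases Denominator for the heterozygosity rate (e.g. the
#'   N-excluded reference length). Must be positive.
#' @return One-row data.frame: `sample_id`, one column per class,
#'   `snp_total`, `transitions`, `transversions`, `ts_tv_ratio` (`NA` when
#'   there are no transversions), `het_snp_count`, `het_rate_permille`.
#' @export
spectrum_summary <- function(snps, sample_id = NULL, callable_bases) {
  stopifnot(callable_bases > 0)
  keep <- if (!is.null(snps$kind)) snps$kind == "snp" else rep(TRUE, length(snps$ref))
  carried <- .carried_mask(snps, sample_id) & keep
  ref <- snps$ref[carried]; alt <- snps$alt[carried]
  cls <- if (length(ref)) collapse_mutation_class(ref, alt) else character(0)
  counts <- table(factor(cls, levels = mutation_classes()))
  ts <- sum(counts[.TS_CLASSES])
  tv <- sum(counts) - ts
  het_n <- if (!is.null(sample_id) && !is.null(snps$gt_class)) {
    j <- match(sample_id, snps$samples)
    sum(snps$gt_class[keep, j] == "het")
  } else if (!is.null(snps$gt_class)) {
    sum(snps$gt_class[keep, , drop = FALSE] == "het")
  } else 0L
  out <- data.frame(sample_id = if (is.null(sample_id)) NA_character_ else sample_id,
                    as.list(as.integer(counts)),
                    snp_total = as.integer(sum(counts)),
                    transitions = as.integer(ts),
                    transversions = as.integer(tv),
                    ts_tv_ratio = if (tv > 0) ts / tv else NA_real_,
                    het_snp_count = as.integer(het_n),
                    het_rate_permille = 1000 * het_n / callable_bases,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[2:7] <- mutation_classes()
  out
}

#' Spectrum summaries for every sample
#'
#' @param snps Kept SNPs (`classified_variants`).
#' @param callable_bases Heterozygosity-rate denominator.
#' @return data.frame with one row per sample.
#' @export
spectrum_table <- function(snps, callable_bases) {
  do.call(rbind, lapply(snps$samples, function(s)
    spectrum_summary(snps, s, callable_bases)))
}

#' Per-sample InDel length and rate summary
#'
#' @param indels Kept InDels: a `classified_variants` object (SNP rows are
#'   ignored) carrying `kind` and `indel_length`.
#' @param sample_id Sample to summarise, or `NULL` to count every record.
#' @param callable_bases Denominator for the per-mille heterozygous-InDel
#'   rate.
#' @return List of class `indel_summary`: `sample_id`, `insertion_count`,
#'   `deletion_count`, `indel_total`, `length_histogram` (named count
#'   vector over lengths 1..50), `length_percentages` (summing to 100),
#'   `het_indel_count`, `het_indel_rate_permille`.
#' @export
indel_summary <- function(indels, sample_id = NULL, callable_bases) {
  stopifnot(callable_bases > 0)
  keep <- if (!is.null(indels$kind)) indels$kind %in% c("insertion", "deletion")
          else rep(TRUE, length(indels$ref))
  carried <- .carried_mask(indels, sample_id) & keep
  len <- indels$indel_length[carried]
  kind <- indels$kind[carried]
  if (length(len) && (any(len < 1L) || any(len > 50L)))
    stop("InDel length outside [1, 50]")
  hist <- table(factor(len, levels = 1:50))
  pct <- if (sum(hist) > 0) 100 * as.numeric(hist) / sum(hist) else rep(0, 50)
  het_n <- if (!is.null(sample_id) && !is.null(indels$gt_class)) {
    j <- match(sample_id, indels$samples)
    sum(indels$gt_class[keep, j] == "het")
  } else if (!is.null(indels$gt_class)) {
    sum(indels$gt_class[keep, , drop = FALSE] == "het")
  } else 0L
  structure(list(
    sample_id = sample_id,
    insertion_count = sum(kind == "insertion"),
    deletion_count = sum(kind == "deletion"),
    indel_total = length(len),
    length_histogram = stats::setNames(as.integer(hist), 1:50),
    length_percentages = stats::setNames(pct, 1:50),
    het_indel_count = as.integer(het_n),
    het_indel_rate_permille = 1000 * het_n / callable_bases
  ), class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf(
    "<indel_summary> %s: %d InDels (%d ins / %d del), 1 bp = %.2f%%, het rate %.3f permille\n",
    if (is.null(x$sample_id)) "(all records)" else x$sample_id,
    x$indel_total, x$insertion_count, x$deletion_count,
    x$length_percentages[["1"]], x$het_indel_rate_permille))
  invisible(x)
}

#' Windowed variant-density track
#'
#' Tiles each chromosome with fixed-size windows (half-open, the last
#' window may be short) and counts kept SNPs and InDels by start position.
#' Output uses BED-like 0-based half-open coordinates.
#'
#' @param variants A `classified_variants` object (uses `kind`), or any
#'   list with `chrom`/`pos` (then everything is counted as `snp_count`).
#' @param chrom_lengths Named vector of chromosome lengths (e.g.
#'   [genome_lengths()]).
#' @param window_size Window width in bases (default 1 Mb).
#' @return data.frame `chrom`, `start`, `end`, `snp_count`, `indel_count`
#'   with attribute `snp_indel_ratio` (named per-chromosome vector, `NA`
#'   where a chromosome has no InDels).
#' @export
window_density <- function(variants, chrom_lengths, window_size = 1e6) {
  stopifnot(window_size >= 1)
  bad <- !variants$chrom %in% names(chrom_lengths)
  if (any(bad))
    stop("variant on unknown chromosome: ", variants$chrom[bad][1], ":",
         variants$pos[bad][1])
  over <- variants$pos > chrom_lengths[variants$chrom] | variants$pos < 1L
  if (any(over))
    stop("variant beyond chromosome length: ", variants$chrom[over][1], ":",
         variants$pos[over][1])
  kind <- if (!is.null(variants$kind)) variants$kind
          else rep("snp", length(variants$pos))
  tracks <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    nw <- max(1L, as.integer(ceiling(L / window_size)))
    start <- (seq_len(nw) - 1L) * window_size
    end <- pmin(start + window_size, L)
    sel <- variants$chrom == ch
    bin <- as.integer(floor((variants$pos[sel] - 1L) / window_size)) + 1L
    is_snp <- kind[sel] == "snp"
    data.frame(chrom = ch, start = start, end = end,
               snp_count = as.integer(tabulate(bin[is_snp], nbins = nw)),
               indel_count = as.integer(tabulate(bin[!is_snp], nbins = nw)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tracks)
  snp_tot <- tapply(out$snp_count, out$chrom, sum)
  ind_tot <- tapply(out$indel_count, out$chrom, sum)
  ratio <- ifelse(ind_tot > 0, snp_tot / ind_tot, NA_real_)
  attr(out, "snp_indel_ratio") <- ratio[names(chrom_lengths)]
  out
}
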