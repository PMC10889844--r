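#' Coding-sequence gene model
#'
#' A gene's coding segments on one chromosome and strand, supporting
#' genomic-to-CDS coordinate projection. Segments are 1-based inclusive
#' genomic intervals, stored sorted by genomic position; the spliced CDS
#' length must be divisible by 3.
#'
#' @param gene_id Locus identifier (e.g. `"LOC132634709"`).
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param segments Two-column matrix (or data.frame) of `start`, `end`
#'   genomic coordinates, 1-based inclusive.
#' @return An object of class `cds_model`.
#' @export
cds_model <- function(gene_id, chromosome, strand, segments) {
  stopifnot(is.character(gene_id), nzchar(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  segments <- as.matrix(segments)
  if (ncol(segments) != 2L) stop("segments must have two columns (start, end)")
  storage.mode(segments) <- "integer"
  colnames(segments) <- c("start", "end")
  segments <- segments[order(segments[, "start"]), , drop = FALSE]
  if (any(segments[, "end"] < segments[, "start"]))
    stop("annotation error in gene ", gene_id, ": segment end < start")
  if (nrow(segments) > 1L &&
      any(segments[-1L, "start"] <= segments[-nrow(segments), "end"]))
    stop("annotation error in gene ", gene_id, ": overlapping CDS segments")
  len <- sum(segments[, "end"] - segments[, "start"] + 1L)
  if (len %% 3L != 0L)
    stop("annotation error in gene ", gene_id, ": CDS length ", len,
         " not divisible by 3")
  structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         segments = segments, cds_length = len),
    class = "cds_model"
  )
}

#' @export
print.cds_model <- function(x, ...) {
  cat(sprintf("<cds_model> %s  %s:%s  %d segment(s), CDS %d bp\n",
              x$gene_id, x$chromosome, x$strand, nrow(x$segments),
              x$cds_length))
  invisible(x)
}

#' Read CDS gene models from a GFF3 file
#'
#' Loads `CDS` features, groups them per gene (via the `gene_id`, `Parent`
#' or `ID` attribute, in that order of preference) and validates each model.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of [cds_model()] objects, keyed by gene id.
#' @export
read_cds_annotation <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features in ", path)
  gene <- rep(NA_character_, nrow(cds))
  for (key in c("gene_id", "Parent", "ID")) {
    if (key %in% names(cds)) {
      val <- cds[[key]]
      if (is.list(val) || inherits(val, "List"))
        val <- vapply(val, function(v) if (length(v)) as.character(v[1]) else NA_character_,
                      character(1))
      val <- as.character(val)
      gene[is.na(gene) & !is.na(val)] <- val[is.na(gene) & !is.na(val)]
    }
  }
  if (anyNA(gene)) stop("CDS feature without a gene identifier in ", path)
  gene <- sub("^(gene[:-]|cds[:-])", "", gene)
  out <- lapply(split(seq_len(nrow(cds)), gene), function(i) {
    chrom <- unique(as.character(cds$seqnames[i]))
    strand <- unique(as.character(cds$strand[i]))
    if (length(chrom) != 1L)
      stop("annotation error: gene ", gene[i[1]], " spans chromosomes")
    if (length(strand) != 1L || !strand %in% c("+", "-"))
      stop("annotation error: gene ", gene[i[1]], " has inconsistent strand")
    cds_model(gene[i[1]], chrom, strand,
              cbind(start = cds$start[i], end = cds$end[i]))
  })
  out[order(names(out))]
}

#' Write CDS gene models to a GFF3 file
#'
#' @param models List of [cds_model()] objects.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_cds_gff3 <- function(models, path, source = "gojivar") {
  lines <- c("##gff-version 3")
  for (m in models) {
    gstart <- min(m$segments[, "start"]); gend <- max(m$segments[, "end"])
    lines <- c(lines, sprintf(
      "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=gene-%s;gene_id=%s",
      m$chromosome, source, gstart, gend, m$strand, m$gene_id, m$gene_id))
    # phase of each segment follows spliced reading-frame order
    segs <- m$segments
    ord <- if (m$strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
    done <- 0L
    for (k in ord) {
      phase <- (3L - done %% 3L) %% 3L
      lines <- c(lines, sprintf(
        "%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s.%d;Parent=gene-%s;gene_id=%s",
        m$chromosome, source, segs[k, "start"], segs[k, "end"], m$strand,
        phase, m$gene_id, k, m$gene_id, m$gene_id))
      done <- done + (segs[k, "end"] - segs[k, "start"] + 1L)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract the spliced, strand-oriented coding sequence of a gene
#'
#' @param cds A [cds_model()].
#' @param genome Named character vector of chromosome sequences.
#' @return The CDS as a single uppercase string, 5' to 3' of the mRNA.
#' @export
cds_sequence <- function(cds, genome) {
  chrom <- genome[[cds$chromosome]]
  if (is.null(chrom)) stop("chromosome ", cds$chromosome, " not in genome")
  parts <- substring(chrom, cds$segments[, "start"], cds$segments[, "end"])
  s <- paste(parts, collapse = "")
  if (cds$strand == "-") s <- reverse_complement(s)
  s
}

#' Project genomic positions onto CDS coordinates
#'
#' CDS positions are 1-based offsets in the spliced coding sequence,
#' counted 5' to 3' of the mRNA: on the minus strand counting starts from
#' the highest genomic coordinate. Positions outside every CDS segment are
#' non-coding and project to `NA` (they are tallied separately downstream,
#' not treated as errors).
#'
#' @param cds A [cds_model()].
#' @param positions Integer vector of 1-based genomic positions.
#' @return data.frame with `genomic_position`, `cds_position`,
#'   `codon_index` and `offset_in_codon` (`NA` rows for non-coding input).
#' @export
project_to_cds <- function(cds, positions) {
  segs <- cds$segments
  seg_len <- segs[, "end"] - segs[, "start"] + 1L
  cum_before <- c(0L, cumsum(seg_len))[seq_len(nrow(segs))]
  cds_pos <- rep(NA_integer_, length(positions))
  for (k in seq_len(nrow(segs))) {
    inside <- !is.na(positions) &
      positions >= segs[k, "start"] & positions <= segs[k, "end"]
    if (!any(inside)) next
    plus_off <- cum_before[k] + (positions[inside] - segs[k, "start"]) + 1L
    cds_pos[inside] <- plus_off
  }
  if (cds$strand == "-") {
    cds_pos <- ifelse(is.na(cds_pos), NA_integer_, cds$cds_length - cds_pos + 1L)
  }
  data.frame(
    genomic_position = positions,
    cds_position = cds_pos,
    codon_index = ifelse(is.na(cds_pos), NA_integer_,
                         as.integer(ceiling(cds_pos / 3))),
    offset_in_codon = ifelse(is.na(cds_pos), NA_integer_,
                             ((cds_pos - 1L) %% 3L) + 1L)
  )
}
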