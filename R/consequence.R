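#' Group coding SNPs by the codon they hit
#'
#' @param cds_positions Integer vector of unique 1-based CDS positions.
#' @return Named list (codon index, ascending) of integer vectors indexing
#'   into `cds_positions`.
#' @export
group_codon_variants <- function(cds_positions) {
  stopifnot(!anyDuplicated(cds_positions))
  idx <- split(seq_along(cds_positions),
               ceiling(cds_positions / 3))
  idx[order(as.integer(names(idx)))]
}

#' Assemble a codon change from the SNPs hitting one codon
#'
#' Builds the reference codon from the coding sequence and substitutes the
#' alternate alleles (given on the coding strand) at their offsets. With
#' one variant position per codon, each alternate allele yields one
#' alternate codon. With several variant positions, the alternate codons
#' enumerated are the allele combinations *attested* by per-sample
#' genotypes when `sample_alleles` is supplied (a sample carrying the
#' alternate at a subset of positions attests the codon with those
#' substitutions and reference bases elsewhere); set `full_enumeration`
#' to enumerate the whole combination space instead.
#'
#' @param gene_id Gene identifier (for messages).
#' @param cds_positions Integer vector of CDS positions, all in one codon.
#' @param alt_alleles List (parallel to `cds_positions`) of character
#'   vectors of alternate bases at each position, coding-strand.
#' @param cds_seq The spliced coding sequence.
#' @param sample_alleles Optional integer matrix, positions x samples:
#'   0 = reference carried only, k = carries the k-th alternate at that
#'   position (NA = missing).
#' @param full_enumeration Enumerate the full Cartesian combination space.
#' @return List of class `codon_change`: `gene_id`, `codon_index`,
#'   `cds_positions`, `ref_codon`, `alt_codons`, `ref_aa`, `alt_aas`,
#'   `effect`, `polarity_change`, `charge_change`.
#' @export
build_codon_change <- function(gene_id, cds_positions, alt_alleles, cds_seq,
                               sample_alleles = NULL,
                               full_enumeration = FALSE) {
  stopifnot(length(cds_positions) >= 1L,
            length(alt_alleles) == length(cds_positions))
  ci <- unique(ceiling(cds_positions / 3))
  if (length(ci) != 1L)
    stop("variant group spans codons ", paste(ci, collapse = ", "),
         " in gene ", gene_id)
  ref_codon <- substr(cds_seq, 3L * ci - 2L, 3L * ci)
  if (nchar(ref_codon) != 3L)
    stop("codon ", ci, " outside coding sequence of gene ", gene_id)
  offs <- ((cds_positions - 1L) %% 3L) + 1L
  ref_bases <- substring(ref_codon, offs, offs)

  combos <- if (length(cds_positions) == 1L) {
    lapply(seq_along(alt_alleles[[1]]), function(k) k)
  } else if (full_enumeration) {
    grid <- do.call(expand.grid, lapply(alt_alleles, function(a) 0:length(a)))
    grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
    lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
  } else if (is.null(sample_alleles)) {
    # no per-sample attestation: substitute all group alleles jointly
    grid <- do.call(expand.grid,
                    lapply(alt_alleles, function(a) seq_along(a)))
    lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
  } else {
    cols <- lapply(seq_len(ncol(sample_alleles)), function(j) {
      v <- sample_alleles[, j]
      if (anyNA(v) || all(v == 0L)) NULL else as.integer(v)
    })
    unique(Filter(Negate(is.null), cols))
  }
  if (length(combos) == 0L)
    stop("no attested alternate combination in gene ", gene_id,
         " codon ", ci)

  alt_codons <- vapply(combos, function(cmb) {
    codon <- strsplit(ref_codon, "", fixed = TRUE)[[1]]
    for (p in seq_along(cds_positions)) {
      k <- if (length(cds_positions) == 1L) cmb else cmb[p]
      if (k > 0L) {
        a <- alt_alleles[[p]][k]
        if (a == ref_bases[p])
          stop("alternate allele equals reference base at CDS position ",
               cds_positions[p], " of gene ", gene_id)
        codon[offs[p]] <- a
      }
    }
    paste(codon, collapse = "")
  }, character(1))
  alt_codons <- unique(alt_codons)

  change <- structure(list(
    gene_id = gene_id, codon_index = ci,
    cds_positions = sort(cds_positions),
    ref_codon = ref_codon, alt_codons = alt_codons,
    ref_aa = NA_character_, alt_aas = NA_character_,
    effect = NA_character_, polarity_change = NA,
    charge_change = NA), class = "codon_change")
  classify_effect(change)
}

#' Classify the effect and property changes of a codon change
#'
#' Translates the reference and alternate codons and fills `effect`
#' (`synonymous` when every alternate amino acid equals the reference,
#' `nonsense` when any alternate is a stop, `stop_loss` when a reference
#' stop is lost, `unknown` for untranslatable codons, else `missense`)
#' plus the polarity/charge flags. A change crosses polarity when polar
#' and nonpolar classes are exchanged; it crosses charge when basic,
#' acidic and uncharged classes are exchanged. Both flags are `FALSE`
#' for synonymous changes.
#'
#' @param change A `codon_change` (or a list with `ref_codon` and
#'   `alt_codons`).
#' @return The `codon_change` with `ref_aa`, `alt_aas`, `effect` and the
#'   property flags filled.
#' @export
classify_effect <- function(change) {
  ref_aa <- translate_codons(change$ref_codon)
  alt_aas <- translate_codons(change$alt_codons)
  change$ref_aa <- ref_aa
  change$alt_aas <- alt_aas
  if (is.na(ref_aa) || anyNA(alt_aas)) {
    change$effect <- "unknown"
    change$polarity_change <- NA
    change$charge_change <- NA
    return(change)
  }
  if (all(alt_aas == ref_aa)) {
    change$effect <- "synonymous"
  } else if (ref_aa == "Stop") {
    change$effect <- "stop_loss"
  } else if (any(alt_aas == "Stop")) {
    change$effect <- "nonsense"    # stop-gaining, never synonymous
  } else {
    change$effect <- "missense"
  }
  if (change$effect == "synonymous") {
    change$polarity_change <- FALSE
    change$charge_change <- FALSE
  } else {
    props <- amino_acid_properties()
    pr <- unname(props[ref_aa]); pa <- unname(props[alt_aas])
    pa <- pa[!is.na(pa)]  # stops carry no property class
    if (is.na(pr) || length(pa) == 0L) {
      change$polarity_change <- FALSE
      change$charge_change <- FALSE
    } else {
      change$polarity_change <- any(
        (pr == "polar" & pa == "nonpolar") | (pr == "nonpolar" & pa == "polar"))
      charge <- function(p) ifelse(p %in% c("basic", "acidic"), p, "uncharged")
      change$charge_change <- any(charge(pr) != charge(pa))
    }
  }
  change
}

#' @export
print.codon_change <- function(x, ...) {
  cat(sprintf("<codon_change> %s codon %d (%s): %s>%s  %s>%s  [%s]%s%s\n",
              x$gene_id, x$codon_index,
              paste(x$cds_positions, collapse = "-"),
              x$ref_codon, paste(x$alt_codons, collapse = "/"),
              x$ref_aa, paste(x$alt_aas, collapse = "/"), x$effect,
              if (isTRUE(x$polarity_change)) " polarity" else "",
              if (isTRUE(x$charge_change)) " charge" else ""))
  invisible(x)
}

#' Coding consequences of kept SNPs for one gene
#'
#' Projects SNPs on the gene's chromosome into CDS space, groups them by
#' codon, assembles codon changes (alternate alleles complemented for
#' minus-strand genes) and classifies each. Non-coding SNPs are tallied,
#' not errors.
#'
#' @param snps Kept SNPs (`classified_variants`).
#' @param cds A [cds_model()].
#' @param genome Named character vector of chromosome sequences.
#' @return List of class `gene_consequences`: `gene_id`, `changes` (list
#'   of `codon_change`), `sites` (data.frame of per-SNP rows:
#'   `genomic_position`, `cds_position`, `codon_index`, `ref`, `alt`
#'   coding-strand, `effect`), `state` (site x sample genotype-class
#'   matrix), `frac` (alt-read percent matrix), `n_noncoding` (SNPs on the
#'   chromosome that fall outside the CDS).
#' @export
gene_consequences <- function(snps, cds, genome) {
  on_chrom <- which(snps$chrom == cds$chromosome & snps$kind == "snp")
  proj <- project_to_cds(cds, snps$pos[on_chrom])
  coding <- !is.na(proj$cds_position)
  idx <- on_chrom[coding]
  proj <- proj[coding, , drop = FALSE]
  seq <- cds_sequence(cds, genome)

  ref <- snps$ref[idx]; alt <- snps$alt[idx]
  if (cds$strand == "-") {
    ref <- complement_bases(ref); alt <- complement_bases(alt)
  }
  ord <- order(proj$cds_position)
  idx <- idx[ord]; proj <- proj[ord, , drop = FALSE]
  ref <- ref[ord]; alt <- alt[ord]

  mism <- substring(seq, proj$cds_position, proj$cds_position) != ref
  if (any(mism))
    stop("reference mismatch in gene ", cds$gene_id, " at CDS position ",
         proj$cds_position[mism][1])

  # collapse same-position records (multiple alternates at one site)
  upos <- unique(proj$cds_position)
  alt_by_pos <- lapply(upos, function(p) unique(alt[proj$cds_position == p]))
  groups <- group_codon_variants(upos)

  state <- snps$gt_class[idx, , drop = FALSE]
  frac <- snps$alt_frac[idx, , drop = FALSE]

  changes <- lapply(groups, function(g) {
    pos_g <- upos[g]
    # attested combinations from per-sample genotype classes
    sample_alleles <- matrix(0L, nrow = length(g), ncol = length(snps$samples))
    for (r in seq_along(g)) {
      rows <- which(proj$cds_position == pos_g[r])
      for (j in seq_along(snps$samples)) {
        cls <- snps$gt_class[idx[rows], j]
        hit <- which(cls %in% c("het", "hom_alt"))
        if (length(hit)) {
          a <- alt[rows][hit[1]]
          sample_alleles[r, j] <- match(a, alt_by_pos[[which(upos == pos_g[r])]])
        } else if (all(cls == "missing")) {
          sample_alleles[r, j] <- NA_integer_
        }
      }
    }
    tryCatch(
      build_codon_change(cds$gene_id, pos_g, alt_by_pos[g], seq,
                         sample_alleles = sample_alleles),
      error = function(e) NULL)
  })
  changes <- Filter(Negate(is.null), changes)

  site_effect <- rep(NA_character_, length(idx))
  for (ch in changes)
    site_effect[proj$cds_position %in% ch$cds_positions] <- ch$effect

  sites <- data.frame(
    genomic_position = snps$pos[idx],
    cds_position = proj$cds_position,
    codon_index = proj$codon_index,
    ref = ref, alt = alt, effect = site_effect,
    stringsAsFactors = FALSE)
  rownames(state) <- rownames(frac) <- NULL
  colnames(state) <- colnames(frac) <- snps$samples
  structure(list(gene_id = cds$gene_id, changes = changes, sites = sites,
                 state = state, frac = frac,
                 n_noncoding = sum(!coding)),
            class = "gene_consequences")
}
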