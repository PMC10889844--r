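#' Default strand-collapsed class probabilities for a target ts/tv ratio
#'
#' The default spectrum keeps the empirically observed ordering
#' (C:G>T:A most frequent, then T:A>C:G, with C:G>G:C rarest) and places
#' exactly half the probability mass on T:A-rooted classes, so that on a
#' base-balanced random genome the realised class frequencies equal the
#' configured ones. The two transition classes are rescaled against the
#' four transversion classes to hit the requested transition/transversion
#' ratio.
#'
#' @param ts_tv Target transitions/transversions ratio.
#' @return Named numeric vector over [mutation_classes()], summing to 1.
#' @export
class_probs_for_tstv <- function(ts_tv = 1.72) {
  stopifnot(ts_tv > 0)
  base <- c("T:A>C:G" = 0.3000, "T:A>G:C" = 0.1100, "C:G>T:A" = 0.3324,
            "C:G>A:T" = 0.1100, "T:A>A:T" = 0.0900, "C:G>G:C" = 0.0576)
  ts <- c("T:A>C:G", "C:G>T:A")
  tv <- setdiff(names(base), ts)
  p_ts <- ts_tv / (1 + ts_tv)
  out <- base
  out[ts] <- base[ts] / sum(base[ts]) * p_ts
  out[tv] <- base[tv] / sum(base[tv]) * (1 - p_ts)
  out[mutation_classes()]
}

#' Default InDel length law
#'
#' Probability per length 1..50: 49.4% at 1 bp, 13.5% at 2 bp, 7.2% at
#' 3 bp, then a geometric tail (ratio 0.8) — under which lengths beyond
#' 12 bp fall below 1% and lengths beyond 32 bp below 0.1%, matching the
#' shape of resequencing InDel spectra.
#'
#' @param p1 Probability of a 1-bp InDel.
#' @return Numeric vector of length 50 summing to 1.
#' @export
default_indel_length_probs <- function(p1 = 0.494) {
  stopifnot(p1 > 0, p1 < 1)
  head <- c(p1, 0.135, 0.072)
  head[2:3] <- head[2:3] * (1 - p1) / (1 - 0.494)  # keep shape if p1 moves
  tail_mass <- 1 - sum(head)
  tail <- 0.8^(0:46)
  c(head, tail_mass * tail / sum(tail))
}

#' Simulation configuration
#'
#' All generator parameters for a two-cohort resequencing simulation.
#' Defaults emulate the study conditions: SNP rate ~8.4 per kb (about 14M
#' SNPs on a 1.67 Gb genome), SNP:InDel ratio ~10, deletions slightly
#' outnumbering insertions, ts/tv 1.72, heterozygous SNP calls at 5.037
#' per mille of the genome, an InDel length law with 49.4% 1-bp events,
#' variant density enriched threefold in the terminal 10% of every
#' chromosome, and about 55% of planted coding SNP sites in a
#' cohort-discriminating configuration.
#'
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @param chromosomes Named integer vector of chromosome lengths.
#' @param n_cultivated,n_wild Samples per cohort (wild may be 0 for
#'   single-cohort profiling runs).
#' @param snp_rate Expected SNP sites per base.
#' @param class_probs Probabilities over [mutation_classes()].
#' @param het_rate_permille Target heterozygous SNP calls per 1000 bases
#'   per sample, measured on filter-passing sites.
#' @param hom_alt_prob Per-sample probability that a site is carried
#'   homozygous-alternate.
#' @param indel_rate Expected InDel sites per base.
#' @param indel_het_rate_permille Target heterozygous InDel calls per
#'   1000 bases per sample.
#' @param indel_length_probs Probability per InDel length 1..50.
#' @param deletion_prob Probability an InDel is a deletion.
#' @param end_fraction Fraction of each chromosome end counted as
#'   terminal.
#' @param end_gradient Multiplicative variant-rate enrichment in the
#'   terminal regions.
#' @param filter_pass_rate Fraction of sites whose DP/MQ evidence passes
#'   the post-call filters.
#' @param n_genes,gene_length Number of CDS genes to place and their
#'   spliced length (divisible by 3).
#' @param coding_snps_per_gene Coding SNP sites planted per gene.
#' @param discriminating_fraction Fraction of planted coding sites whose
#'   states separate the cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chromosomes = c(sim1 = 1e6, sim2 = 1e6),
                              n_cultivated = 5L, n_wild = 3L,
                              snp_rate = 0.0084,
                              class_probs = class_probs_for_tstv(1.72),
                              het_rate_permille = 5.037,
                              hom_alt_prob = 0.25,
                              indel_rate = 0.00084,
                              indel_het_rate_permille = 0.381,
                              indel_length_probs = default_indel_length_probs(),
                              deletion_prob = 0.538,
                              end_fraction = 0.1,
                              end_gradient = 3,
                              filter_pass_rate = 0.95,
                              n_genes = 3L, gene_length = 900L,
                              coding_snps_per_gene = 10L,
                              discriminating_fraction = 0.55) {
  stopifnot(length(chromosomes) >= 1L, !is.null(names(chromosomes)),
            all(chromosomes >= 1000), n_cultivated >= 1L, n_wild >= 0L,
            snp_rate > 0, indel_rate >= 0,
            het_rate_permille >= 0, hom_alt_prob >= 0,
            end_fraction > 0, end_fraction < 0.5, end_gradient >= 1,
            filter_pass_rate > 0, filter_pass_rate <= 1,
            n_genes >= 0L, gene_length %% 3L == 0L,
              discriminating_fraction >= 0, discriminating_fraction <= 1)
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1")
  if (abs(sum(indel_length_probs) - 1) > 1e-8 ||
      length(indel_length_probs) != 50L)
    stop("indel_length_probs must have 50 entries summing to 1")
  p_het <- het_rate_permille / 1000 / (snp_rate * filter_pass_rate)
  if (p_het + hom_alt_prob > 1)
    stop("het target plus hom_alt_prob exceeds 1: raise snp_rate")
  seed <- as.integer(seed %% (.Machine$integer.max - 2L))
  samples <- c(if (n_cultivated > 0) paste0("Lb", seq_len(n_cultivated)),
               if (n_wild > 0) paste0("Lb", n_cultivated + seq_len(n_wild), "w"))
  cohorts <- stats::setNames(
    rep(c("cultivated", "wild"), c(n_cultivated, n_wild)), samples)
  structure(list(
    seed = seed, chromosomes = chromosomes,
    n_cultivated = n_cultivated, n_wild = n_wild,
    samples = samples, cohorts = cohorts,
    snp_rate = snp_rate, class_probs = class_probs,
    het_rate_permille = het_rate_permille, p_het = p_het,
    hom_alt_prob = hom_alt_prob,
    indel_rate = indel_rate,
    indel_het_rate_permille = indel_het_rate_permille,
    p_het_indel = if (indel_rate > 0)
      min(1, indel_het_rate_permille / 1000 / (indel_rate * filter_pass_rate))
      else 0,
    indel_length_probs = indel_length_probs,
    deletion_prob = deletion_prob,
    end_fraction = end_fraction, end_gradient = end_gradient,
    filter_pass_rate = filter_pass_rate,
    n_genes = n_genes, gene_length = gene_length,
    coding_snps_per_gene = coding_snps_per_gene,
    discriminating_fraction = discriminating_fraction),
    class = "simulation_config")
}

.set_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           sample.kind = "Rejection")
}

#' Simulate a genome and its CDS annotation
#'
#' Uniform-random nucleotide chromosomes, with `n_genes` non-overlapping
#' CDS genes (single- or two-segment, strand random, spliced length
#' `gene_length`) placed round-robin across chromosomes. RNG draws:
#' chromosome sequences first (in order), then per-gene placement.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named character vector) and `cds` (named
#'   list of [cds_model()]).
#' @export
simulate_genome <- function(config) {
  .set_seed(config$seed)
  genome <- vapply(config$chromosomes, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(genome) <- names(config$chromosomes)

  cds <- list()
  occupied <- lapply(config$chromosomes, function(L) cbind(start = integer(0),
                                                           end = integer(0)))
  if (config$n_genes > 0L) {
    for (g in seq_len(config$n_genes)) {
      ch <- ((g - 1L) %% length(config$chromosomes)) + 1L
      L <- config$chromosomes[[ch]]
      two_seg <- stats::runif(1) < 0.5
      intron <- if (two_seg) sample(50:200, 1L) else 0L
      span <- config$gene_length + intron
      if (span + 2L > L)
        stop("config error: gene span ", span, " exceeds chromosome ",
             names(config$chromosomes)[ch])
      placed <- FALSE
      for (try in 1:200) {
        start <- sample.int(L - span, 1L)
        end <- start + span - 1L
        occ <- occupied[[ch]]
        if (nrow(occ) == 0L || all(end < occ[, "start"] | start > occ[, "end"])) {
          placed <- TRUE; break
        }
      }
      if (!placed)
        stop("config error: could not place gene ", g,
             " without overlap; reduce n_genes or gene_length")
      occupied[[ch]] <- rbind(occupied[[ch]], cbind(start = start, end = end))
      segs <- if (two_seg) {
        l1 <- 3L * sample.int(config$gene_length / 3L - 1L, 1L)
        rbind(c(start, start + l1 - 1L),
              c(start + l1 + intron, end))
      } else rbind(c(start, end))
      strand <- sample(c("+", "-"), 1L)
      id <- sprintf("GENE%03d", g)
      cds[[id]] <- cds_model(id, names(config$chromosomes)[ch], strand, segs)
    }
  }
  list(genome = genome, cds = cds)
}

# end-weighted positions: terminal fraction f at each end carries rate
# multiplier g; positions drawn by region then uniformly (without
# replacement, so site counts are not thinned by collisions) within it
.draw_positions <- function(n, L, f, g, lo = 1L, hi = NULL) {
  if (is.null(hi)) hi <- L
  ends <- floor(L * f)
  mass <- c(g * ends, L - 2 * ends, g * ends)
  region <- sample.int(3L, n, replace = TRUE, prob = mass / sum(mass))
  n1 <- sum(region == 1L); n2 <- sum(region == 2L); n3 <- sum(region == 3L)
  if (n1 > ends || n3 > ends || n2 > L - 2L * ends)
    stop("config error: variant rate too high for chromosome length")
  pos <- integer(n)
  pos[region == 1L] <- sample.int(ends, n1, replace = FALSE)
  pos[region == 2L] <- ends + sample.int(L - 2L * ends, n2, replace = FALSE)
  pos[region == 3L] <- L - ends + sample.int(ends, n3, replace = FALSE)
  pos[pos < lo] <- lo
  pos[pos > hi] <- hi
  pos
}

# class draw conditioned on the reference base at each site
.draw_classes <- function(ref, class_probs) {
  cls <- character(length(ref))
  ta <- ref %in% c("T", "A")
  ta_classes <- c("T:A>C:G", "T:A>G:C", "T:A>A:T")
  cg_classes <- c("C:G>T:A", "C:G>A:T", "C:G>G:C")
  if (any(ta)) {
    p <- class_probs[ta_classes]
    cls[ta] <- sample(ta_classes, sum(ta), replace = TRUE, prob = p / sum(p))
  }
  if (any(!ta)) {
    p <- class_probs[cg_classes]
    cls[!ta] <- sample(cg_classes, sum(!ta), replace = TRUE, prob = p / sum(p))
  }
  cls
}

# alternate base implied by (ref base, collapsed class)
.ALT_FROM_CLASS <- local({
  m <- matrix(NA_character_, nrow = 4, ncol = 6,
              dimnames = list(c("A", "C", "G", "T"),
                              c("T:A>C:G", "T:A>G:C", "C:G>T:A",
                                "C:G>A:T", "T:A>A:T", "C:G>G:C")))
  m["T", "T:A>C:G"] <- "C"; m["A", "T:A>C:G"] <- "G"
  m["T", "T:A>G:C"] <- "G"; m["A", "T:A>G:C"] <- "C"
  m["T", "T:A>A:T"] <- "A"; m["A", "T:A>A:T"] <- "T"
  m["C", "C:G>T:A"] <- "T"; m["G", "C:G>T:A"] <- "A"
  m["C", "C:G>A:T"] <- "A"; m["G", "C:G>A:T"] <- "T"
  m["C", "C:G>G:C"] <- "G"; m["G", "C:G>G:C"] <- "C"
  m
})

#' Simulate two-cohort variant calls over a simulated genome
#'
#' Generates SNP and InDel records with the configured spectrum,
#' heterozygosity, length law, chromosome-end density enrichment and
#' filter pass rate, plus planted coding SNP sites inside the annotated
#' genes of which a configured fraction separates the cohorts (one cohort
#' uniformly in one genotype state class, the other uniformly in a
#' different class). Draw order per chromosome: SNP count, positions,
#' classes, evidence, then per-sample genotypes; then InDels; then coding
#' sites — so enlarging later stages never perturbs earlier draws.
#'
#' @param config A [simulation_config()].
#' @param genome,cds As returned by [simulate_genome()].
#' @return A [variant_set()] (raw GT/AD strings, ready for
#'   [split_multiallelic()]), with attribute `truth`: a list with the
#'   planted coding-site table (`gene_id`, `chrom`, `pos`,
#'   `discriminating`).
#' @export
simulate_cohort_variants <- function(config, genome, cds) {
  .set_seed(config$seed + 1L)
  ns <- length(config$samples)
  recs <- list()

  draw_evidence <- function(n) {
    pass <- stats::runif(n) < config$filter_pass_rate
    dp <- integer(n); mq <- numeric(n)
    dp[pass] <- 5L + stats::rpois(sum(pass), 10)
    mq[pass] <- round(stats::runif(sum(pass), 25, 60), 2)
    fail_dp <- !pass & stats::runif(n) < 0.5
    fail_mq <- !pass & !fail_dp
    dp[fail_dp] <- sample.int(4L, sum(fail_dp), replace = TRUE)
    mq[fail_dp] <- round(stats::runif(sum(fail_dp), 25, 60), 2)
    dp[fail_mq] <- 5L + stats::rpois(sum(fail_mq), 10)
    mq[fail_mq] <- round(stats::runif(sum(fail_mq), 2, 20), 2)
    list(dp = dp, mq = mq)
  }

  draw_genotypes <- function(n, dp, p_het) {
    # per sample in order; AD strings for a diploid biallelic site
    gt <- matrix("0/0", n, ns); ad <- matrix(NA_character_, n, ns)
    p <- c(het = p_het, hom_alt = config$hom_alt_prob)
    p <- c(p, hom_ref = max(0, 1 - sum(p)))
    for (j in seq_len(ns)) {
      cls <- sample(names(p), n, replace = TRUE, prob = p)
      altd <- integer(n)
      het <- cls == "het"
      altd[het] <- stats::rbinom(sum(het), dp[het], 0.5)
      altd[cls == "hom_alt"] <- dp[cls == "hom_alt"]
      gt[, j] <- c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0")[cls]
      ad[, j] <- paste0(dp - altd, ",", altd)
    }
    list(gt = gt, ad = ad)
  }

  base_at <- function(ch, pos) {
    substring(genome[[ch]], pos, pos)
  }

  for (ch in names(config$chromosomes)) {
    L <- config$chromosomes[[ch]]
    # --- SNPs ---
    n_snp <- stats::rpois(1, config$snp_rate * L)
    if (n_snp > 0) {
      pos <- sort(unique(.draw_positions(n_snp, L, config$end_fraction,
                                         config$end_gradient)))
      n_snp <- length(pos)
      ref <- base_at(ch, pos)
      cls <- .draw_classes(ref, config$class_probs)
      alt <- .ALT_FROM_CLASS[cbind(ref, cls)]
      ev <- draw_evidence(n_snp)
      gt <- draw_genotypes(n_snp, ev$dp, config$p_het)
      recs[[length(recs) + 1L]] <- list(
        chrom = rep(ch, n_snp), pos = pos, ref = ref, alt = alt,
        dp = ev$dp, mq = ev$mq, gt = gt$gt, ad = gt$ad,
        origin = rep("background", n_snp))
    }
    # --- InDels ---
    n_ind <- if (config$indel_rate > 0) stats::rpois(1, config$indel_rate * L)
             else 0L
    if (n_ind > 0) {
      pos <- sort(unique(.draw_positions(n_ind, L, config$end_fraction,
                                         config$end_gradient,
                                         lo = 1L, hi = L - 51L)))
      n_ind <- length(pos)
      len <- sample.int(50L, n_ind, replace = TRUE,
                        prob = config$indel_length_probs)
      is_del <- stats::runif(n_ind) < config$deletion_prob
      anchor <- base_at(ch, pos)
      ref <- anchor; alt <- anchor
      if (any(is_del))
        ref[is_del] <- substring(genome[[ch]], pos[is_del],
                                 pos[is_del] + len[is_del])
      if (any(!is_del)) {
        ins_seq <- vapply(len[!is_del], function(l)
          paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                collapse = ""), character(1))
        alt[!is_del] <- paste0(anchor[!is_del], ins_seq)
      }
      ev <- draw_evidence(n_ind)
      gt <- draw_genotypes(n_ind, ev$dp, config$p_het_indel)
      recs[[length(recs) + 1L]] <- list(
        chrom = rep(ch, n_ind), pos = pos, ref = ref, alt = alt,
        dp = ev$dp, mq = ev$mq, gt = gt$gt, ad = gt$ad,
        origin = rep("background", n_ind))
    }
  }

  # --- planted coding SNP sites ---
  truth <- data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), discriminating = logical(0))
  for (m in cds) {
    k <- min(config$coding_snps_per_gene, m$cds_length %/% 3L)
    if (k == 0L) next
    codons <- sort(sample.int(m$cds_length %/% 3L, k))
    offs <- sample.int(3L, k, replace = TRUE)
    cds_pos <- (codons - 1L) * 3L + offs
    # map CDS positions back to genomic coordinates
    segs <- m$segments
    seg_len <- segs[, "end"] - segs[, "start"] + 1L
    cum <- c(0L, cumsum(seg_len))
    plus_pos <- if (m$strand == "+") cds_pos else m$cds_length - cds_pos + 1L
    gpos <- vapply(plus_pos, function(p) {
      s <- max(which(cum < p))
      segs[s, "start"] + (p - cum[s]) - 1L
    }, integer(1))
    ref_g <- vapply(gpos, function(p) base_at(m$chromosome, p), character(1))
    alt_g <- vapply(ref_g, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    disc <- stats::runif(k) < config$discriminating_fraction
    ev <- draw_evidence(k)
    gt <- matrix("0/0", k, ns); ad <- matrix(NA_character_, k, ns)
    is_wild <- config$cohorts[config$samples] == "wild"
    pattern_a <- stats::runif(k) < 0.5
    for (i in seq_len(k)) {
      if (disc[i] && any(is_wild)) {
        # cultivated het / wild hom-ref, or cultivated hom-alt / wild het
        gt[i, ] <- if (pattern_a[i]) ifelse(is_wild, "0/0", "0/1")
                   else ifelse(is_wild, "0/1", "1/1")
      } else if (disc[i]) {
        gt[i, ] <- "0/1"
      } else {
        if (stats::runif(1) < 0.5) {
          gt[i, ] <- "0/1"                       # uniform het everywhere
        } else {
          gt[i, ] <- ifelse(is_wild, sample(c("0/0", "0/1"), ns,
                                            replace = TRUE)[seq_len(ns)],
                            "0/1")
          wgt <- gt[i, is_wild]
          if (length(wgt) > 1L && length(unique(wgt)) == 1L)
            gt[i, which(is_wild)[1]] <- setdiff(c("0/0", "0/1"), wgt[1])
        }
      }
      het_j <- gt[i, ] == "0/1"
      altd <- integer(ns)
      altd[het_j] <- stats::rbinom(sum(het_j), ev$dp[i], 0.5)
      altd[gt[i, ] == "1/1"] <- ev$dp[i]
      ad[i, ] <- paste0(ev$dp[i] - altd, ",", altd)
    }
    recs[[length(recs) + 1L]] <- list(
      chrom = rep(m$chromosome, k), pos = gpos, ref = ref_g, alt = alt_g,
      dp = ev$dp, mq = ev$mq, gt = gt, ad = ad,
      origin = rep("coding", k))
    truth <- rbind(truth, data.frame(
      gene_id = m$gene_id, chrom = m$chromosome, pos = gpos,
      discriminating = disc))
  }

  chrom <- unlist(lapply(recs, `[[`, "chrom"))
  pos <- unlist(lapply(recs, `[[`, "pos"))
  ref <- unlist(lapply(recs, `[[`, "ref"))
  alt <- unlist(lapply(recs, `[[`, "alt"))
  dp <- unlist(lapply(recs, `[[`, "dp"))
  mq <- unlist(lapply(recs, `[[`, "mq"))
  gt <- do.call(rbind, lapply(recs, `[[`, "gt"))
  ad <- do.call(rbind, lapply(recs, `[[`, "ad"))
  origin <- unlist(lapply(recs, `[[`, "origin"))

  # drop background records colliding with planted coding sites
  key <- paste(chrom, pos)
  coding <- origin == "coding"
  keep <- coding | !(key %in% key[coding])
  ord <- order(match(chrom, names(config$chromosomes)), pos)
  ord <- ord[keep[ord]]

  out <- variant_set(chrom[ord], pos[ord], ref[ord], alt[ord], dp[ord],
                     mq[ord], gt[ord, , drop = FALSE],
                     ad[ord, , drop = FALSE], config$samples)
  attr(out, "truth") <- list(coding_sites = truth)
  out
}

#' Run a full simulation and write its outputs
#'
#' Writes `genome.fa`, `genes.gff3`, `variants.vcf`, `cohorts.tsv` and a
#' `manifest.json` into a run directory. Outputs are byte-identical for a
#' fixed config.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `genome`, `cds`, `variants` and the
#'   output `paths`.
#' @export
simulate_run <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  variants <- simulate_cohort_variants(config, sim$genome, sim$cds)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "variants.vcf"),
    cohorts = file.path(dir, "cohorts.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_fasta(sim$genome, paths$fasta)
  write_cds_gff3(sim$cds, paths$gff)
  write_vcf(variants, paths$vcf, contig_lengths = genome_lengths(sim$genome))
  write_cohorts(config$cohorts, paths$cohorts)
  manifest <- list(
    seed = config$seed,
    chromosomes = as.list(config$chromosomes),
    samples = config$samples,
    n_variants = n_variants(variants),
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(genome = sim$genome, cds = sim$cds, variants = variants,
                 paths = paths))
}
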