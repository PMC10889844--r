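#' Render a per-gene table mirroring the published layout
#'
#' Writes one row per site with the printed column order: row number,
#' position in coding sequence, codon (reference/alternates), amino acid,
#' per-sample state tokens (`hNN` for heterozygous calls, amino acid for
#' homozygous states), the discriminating flag and the effect — diffable
#' against the packaged fixtures.
#'
#' @param matrix A `site_state_matrix`.
#' @param report Matching [gene_discrimination_report()] (optional).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
render_gene_table <- function(matrix, report = NULL, path) {
  rows <- matrix$rows
  n <- nrow(rows)
  cells <- matrix(NA_character_, nrow = n, ncol = length(matrix$samples))
  for (r in seq_len(n)) {
    st <- matrix$states[[r]]; fr <- matrix$fracs[[r]]
    cells[r, ] <- vapply(seq_len(ncol(st)), function(j) {
      toks <- vapply(seq_len(nrow(st)), function(p) {
        switch(st[p, j],
               het = sprintf("h%d", as.integer(round(fr[p, j]))),
               hom_ref = rows$ref_aa[r],
               hom_alt = strsplit(rows$alt_aas[r], "/", fixed = TRUE)[[1]][1],
               "NA")
      }, character(1))
      if (length(unique(toks)) == 1L) toks[1] else paste(toks, collapse = "/")
    }, character(1))
  }
  out <- data.frame(
    nr = seq_len(n),
    position = rows$position_label,
    codon = paste(rows$ref_codon, rows$alt_codons, sep = "/"),
    amino_acid = paste0(rows$ref_aa, "/", rows$alt_aas,
                        ifelse(rows$effect == "synonymous", " (silent)", "")),
    effect = rows$effect,
    stringsAsFactors = FALSE)
  colnames(cells) <- matrix$samples
  out <- cbind(out, cells)
  if (!is.null(report))
    out$discriminating <- out$position %in% report$discriminating_positions
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole analysis pipeline
#'
#' Orchestrates input loading (or simulation), variant QC, spectrum and
#' InDel summaries, density tracks, and per-gene consequence plus
#' discrimination reports, writing tabular outputs and a machine-readable
#' `summary.json` into an output directory.
#'
#' Exactly one of the file-input arguments (`fasta` + `gff` + `vcf` +
#' `cohorts`) or `simulate` must be provided. Alternatively `site_tables`
#' runs the fixture-driven mode on packaged (or user) gene state tables,
#' which needs no genome.
#'
#' @param fasta,gff,vcf,cohorts Input file paths.
#' @param simulate A [simulation_config()] to generate inputs instead.
#' @param site_tables Character vector of site-table paths for
#'   fixture-driven mode (used together with `cohorts` or the packaged
#'   cohort table).
#' @param thresholds A [filter_thresholds()].
#' @param window_size Density window width in bases.
#' @param out_dir Output directory.
#' @return Invisibly, the summary list (also serialised to
#'   `summary.json`).
#' @export
run_pipeline <- function(fasta = NULL, gff = NULL, vcf = NULL,
                         cohorts = NULL, simulate = NULL,
                         site_tables = NULL,
                         thresholds = filter_thresholds(),
                         window_size = 1e6, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  summary <- list()

  if (!is.null(site_tables)) {
    cohort_map <- read_cohorts(
      if (is.null(cohorts))
        system.file("extdata", "cohorts.tsv", package = "gojivar",
                    mustWork = TRUE)
      else cohorts)
    summary$genes <- list()
    for (tab in site_tables) {
      m <- read_site_table(tab)
      for (note in m$notes) say("[site-table] %s: %s", m$gene_id, note)
      rep <- gene_discrimination_report(m, cohort_map)
      render_gene_table(m, rep, file.path(out_dir,
                                          paste0(m$gene_id, "_sites.tsv")))
      say("[discriminate] %s: %d of %d sites discriminate (%d%%)",
          m$gene_id, rep$n_discriminating, rep$n_sites,
          rep$percent_discriminating)
      summary$genes[[m$gene_id]] <- list(
        n_sites = rep$n_sites,
        n_discriminating = rep$n_discriminating,
        percent_discriminating = rep$percent_discriminating,
        non_discriminating_positions = rep$non_discriminating_positions,
        n_synonymous = sum(m$rows$effect == "synonymous"),
        cross_tab = as.list(as.data.frame(rep$cross_tab)))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(summary))
  }

  if (!is.null(simulate)) {
    if (!inherits(simulate, "simulation_config"))
      stop("configuration error: 'simulate' must be a simulation_config")
    say("[simulate] seed %d, %d chromosome(s), %d sample(s)",
        simulate$seed, length(simulate$chromosomes),
        length(simulate$samples))
    sim <- simulate_run(simulate, file.path(out_dir, "sim"))
    genome <- sim$genome; cds <- sim$cds
    variants <- sim$variants
    cohort_map <- simulate$cohorts
  } else {
    if (is.null(fasta) || is.null(gff) || is.null(vcf) || is.null(cohorts))
      stop("configuration error: provide fasta, gff, vcf and cohorts, ",
           "or a simulate config")
    cohort_map <- read_cohorts(cohorts)     # fail fast on config errors
    genome <- read_fasta(fasta)
    cds <- read_cds_annotation(gff)
    variants <- read_vcf(vcf)
  }

  say("[io] %d variant record(s), %d sample(s)", n_variants(variants),
      length(variants$samples))
  qc <- classify_variants(split_multiallelic(variants), thresholds)
  utils::write.table(qc$dropped, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("[qc] kept %d record(s), dropped %d", n_variants(qc$kept),
      nrow(qc$dropped))

  callable <- callable_bases(genome)
  spec <- spectrum_table(qc$kept, callable)
  utils::write.table(spec, file.path(out_dir, "spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  indel_rows <- lapply(variants$samples, function(s) {
    isum <- indel_summary(qc$kept, s, callable)
    data.frame(sample_id = s, insertion_count = isum$insertion_count,
               deletion_count = isum$deletion_count,
               pct_1bp = isum$length_percentages[["1"]],
               pct_2bp = isum$length_percentages[["2"]],
               pct_3bp = isum$length_percentages[["3"]],
               het_indel_rate_permille = isum$het_indel_rate_permille)
  })
  indels <- do.call(rbind, indel_rows)
  utils::write.table(indels, file.path(out_dir, "indel_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dens <- window_density(qc$kept, genome_lengths(genome), window_size)
  utils::write.table(dens, file.path(out_dir, "density.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  say("[spectrum] mean ts/tv %.3f, mean het rate %.3f permille",
      mean(spec$ts_tv_ratio, na.rm = TRUE),
      mean(spec$het_rate_permille))

  summary$samples <- spec$sample_id
  summary$spectrum <- spec
  summary$indels <- indels
  summary$snp_indel_ratio <- as.list(attr(dens, "snp_indel_ratio"))
  summary$genes <- list()
  if (length(cds) && length(unique(cohort_map)) == 2L) {
    for (m in cds) {
      sm <- site_matrix_from_variants(qc$kept, m, genome)
      if (is.null(sm$rows) || nrow(sm$rows) == 0L) next
      rep <- gene_discrimination_report(sm, cohort_map)
      render_gene_table(sm, rep,
                        file.path(out_dir, paste0(m$gene_id, "_sites.tsv")))
      say("[discriminate] %s: %d of %d sites discriminate",
          m$gene_id, rep$n_discriminating, rep$n_sites)
      summary$genes[[m$gene_id]] <- list(
        n_sites = rep$n_sites, n_discriminating = rep$n_discriminating,
        percent_discriminating = rep$percent_discriminating)
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(summary)
}
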