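#' Three-way state of a sample at a variant site
#'
#' @param genotype One of `hom_ref`, `hom_alt`, `het`, `missing`.
#' @param alt_read_fraction Optional percentage of reads supporting the
#'   alternate allele (meaningful for heterozygous calls; reported for
#'   transparency only — the discrimination rule ignores it).
#' @return List of class `site_state` with `class` and
#'   `alt_read_fraction`; genotype `missing` yields class `unassessable`.
#' @export
site_state <- function(genotype, alt_read_fraction = NA_real_) {
  if (!genotype %in% c("hom_ref", "hom_alt", "het", "missing"))
    stop("unknown genotype: ", genotype)
  if (!is.na(alt_read_fraction) &&
      (alt_read_fraction < 0 || alt_read_fraction > 100))
    stop("alt_read_fraction must lie in [0, 100]")
  structure(list(
    class = if (genotype == "missing") "unassessable" else genotype,
    alt_read_fraction = alt_read_fraction), class = "site_state")
}

#' Does a site's state pattern discriminate the two cohorts?
#'
#' The rule induced from the published gene tables: a site discriminates
#' the cohorts when every cultivated sample shares one state class, every
#' wild sample shares one state class, and the two classes differ.
#' Alt-read fractions play no role (heterozygous is heterozygous
#' regardless of the percentage).
#'
#' @param states Named character vector of state classes (`hom_ref`,
#'   `hom_alt`, `het`; `missing`/`unassessable`/`NA` = unassessable),
#'   names are sample ids — or a matrix with one row per constituent
#'   position of a multi-position site (the site discriminates if any
#'   position does).
#' @param cohorts Named character vector sample -> {cultivated, wild}.
#' @return `TRUE`, `FALSE`, or `NA` when a whole cohort (or any sample at
#'   every position) is unassessable.
#' @export
discriminates <- function(states, cohorts) {
  if (is.matrix(states)) {
    res <- apply(states, 1L, discriminates, cohorts = cohorts)
    if (any(res %in% TRUE)) return(TRUE)
    if (anyNA(res)) return(NA)
    return(FALSE)
  }
  if (is.null(names(states))) stop("states must be named by sample id")
  miss <- setdiff(names(cohorts), names(states))
  if (length(miss))
    stop("no state for sample(s): ", paste(miss, collapse = ", "))
  states <- states[names(cohorts)]
  states[states %in% c("missing", "unassessable")] <- NA_character_
  cult <- states[cohorts == "cultivated"]
  wild <- states[cohorts == "wild"]
  if (length(cult) == 0L || length(wild) == 0L)
    stop("discrimination needs at least one sample per cohort")
  if (all(is.na(cult)) || all(is.na(wild))) return(NA)
  if (anyNA(cult) || anyNA(wild)) return(NA)
  uc <- unique(cult); uw <- unique(wild)
  length(uc) == 1L && length(uw) == 1L && uc != uw
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-gene cohort-discrimination report
#'
#' Applies [discriminates()] to every site of a site-state matrix and
#' cross-tabulates the result against the silent/non-silent effect
#' classification. Sites with any unassessable sample in either cohort
#' are excluded from the denominator and listed separately.
#'
#' @param matrix A `site_state_matrix` (see [read_site_table()] or
#'   [site_matrix_from_variants()]) with effects classified.
#' @param cohorts Named character vector sample -> {cultivated, wild};
#'   every matrix sample must be labelled.
#' @return List of class `discrimination_report`: `gene_id`, `n_sites`,
#'   `n_discriminating`, `percent_discriminating` (integer, half-up),
#'   `discriminating_positions`, `non_discriminating_positions`
#'   (printed position labels), `excluded_positions`, and `cross_tab`
#'   (2 x 2 matrix discriminating x silent).
#' @export
gene_discrimination_report <- function(matrix, cohorts) {
  stopifnot(inherits(matrix, "site_state_matrix"))
  miss <- setdiff(matrix$samples, names(cohorts))
  if (length(miss))
    stop("cohort map missing sample(s): ", paste(miss, collapse = ", "))
  cohorts <- cohorts[matrix$samples]
  if (anyNA(matrix$rows$effect))
    stop("matrix rows carry no effect classification")
  verdict <- vapply(matrix$states, function(st) {
    colnames(st) <- matrix$samples
    v <- discriminates(st, cohorts)
    if (is.na(v)) NA else v
  }, logical(1))
  lab <- matrix$rows$position_label
  silent <- matrix$rows$effect == "synonymous"
  assessed <- !is.na(verdict)
  ct <- table(
    discriminating = factor(verdict[assessed], levels = c(TRUE, FALSE),
                            labels = c("discriminating", "non_discriminating")),
    effect = factor(silent[assessed], levels = c(TRUE, FALSE),
                    labels = c("silent", "non_silent")))
  n_sites <- sum(assessed)
  n_disc <- sum(verdict[assessed])
  structure(list(
    gene_id = matrix$gene_id,
    n_sites = n_sites,
    n_discriminating = n_disc,
    percent_discriminating = as.integer(round_half_up(
      if (n_sites > 0) 100 * n_disc / n_sites else 0)),
    discriminating_positions = lab[assessed & verdict %in% TRUE],
    non_discriminating_positions = lab[assessed & verdict %in% FALSE],
    excluded_positions = lab[!assessed],
    cross_tab = unclass(ct)), class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> %s: %d of %d sites discriminate (%d%%)\n",
              x$gene_id, x$n_discriminating, x$n_sites,
              x$percent_discriminating))
  cat("  non-discriminating:",
      paste(x$non_discriminating_positions, collapse = ", "), "\n")
  print(x$cross_tab)
  invisible(x)
}

#' Build a site-state matrix from classified variants
#'
#' Turns the coding SNPs of one gene (per-sample genotype classes from a
#' kept, classified variant set) into the same structure the fixture
#' loader produces, one row per codon-grouped site, so that
#' [gene_discrimination_report()] applies uniformly to simulated and
#' fixture data.
#'
#' @param snps Kept SNPs (`classified_variants`).
#' @param cds A [cds_model()].
#' @param genome Named character vector of chromosome sequences.
#' @return A `site_state_matrix`.
#' @export
site_matrix_from_variants <- function(snps, cds, genome) {
  gc <- gene_consequences(snps, cds, genome)
  groups <- split(seq_len(nrow(gc$sites)), gc$sites$codon_index)
  groups <- groups[order(as.integer(names(groups)))]
  chg_by_codon <- stats::setNames(gc$changes,
                                  vapply(gc$changes, `[[`, 0, "codon_index"))
  rows <- list(); states <- list(); fracs <- list()
  for (g in groups) {
    pos <- gc$sites$cds_position[g]
    ci <- as.character(gc$sites$codon_index[g[1]])
    ch <- chg_by_codon[[ci]]
    if (is.null(ch)) next
    rows[[length(rows) + 1L]] <- data.frame(
      position_label = if (length(pos) > 1L)
        paste(min(pos), max(pos), sep = "-") else as.character(pos),
      ref_codon = ch$ref_codon,
      alt_codons = paste(ch$alt_codons, collapse = "/"),
      ref_aa = ch$ref_aa,
      alt_aas = paste(ch$alt_aas, collapse = "/"),
      effect = ch$effect,
      polarity_change = ch$polarity_change,
      charge_change = ch$charge_change,
      stringsAsFactors = FALSE)
    st <- gc$state[g, , drop = FALSE]
    st[st == "missing"] <- "unassessable"
    states[[length(states) + 1L]] <- st
    fracs[[length(fracs) + 1L]] <- gc$frac[g, , drop = FALSE]
  }
  structure(list(
    gene_id = gc$gene_id,
    rows = do.call(rbind, rows),
    states = states, fracs = fracs,
    samples = colnames(gc$state),
    positions = lapply(groups, function(g) gc$sites$cds_position[g]),
    notes = character(0)), class = "site_state_matrix")
}

#' @export
print.site_state_matrix <- function(x, ...) {
  cat(sprintf("<site_state_matrix> %s: %d site(s) x %d sample(s)\n",
              x$gene_id, length(x$states), length(x$samples)))
  if (length(x$notes)) cat(paste0("  note: ", x$notes, "\n"), sep = "")
  invisible(x)
}
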