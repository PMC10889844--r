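#' Paths to the packaged gene site tables
#'
#' The three per-gene SNP state tables published for the BODYGUARD genes
#' on chromosomes 4, 8 and 9 are packaged verbatim as tab-separated
#' fixtures, together with an auditable corrections file that normalises
#' the handful of typographic errors in the printed tables (for example a
#' heterozygous percentage above 100, or a reference amino acid that
#' contradicts the printed codons).
#'
#' @return Named character vector of file paths (names are gene ids).
#' @export
bdg_table_paths <- function() {
  files <- c(
    LOC132634709 = "bdg_sites_chr4_LOC132634709.tsv",
    LOC132607278 = "bdg_sites_chr8_LOC132607278.tsv",
    LOC132609965 = "bdg_sites_chr9_LOC132609965.tsv")
  vapply(files, function(f)
    system.file("extdata", f, package = "gojivar", mustWork = TRUE),
    character(1))
}

.default_corrections <- function() {
  system.file("extdata", "table_corrections.tsv", package = "gojivar",
              mustWork = TRUE)
}

.strip_token <- function(x) gsub("\\s+", "", x)

# "Leu(CTA)" -> list(aa="Leu", codon="CTA"); "h69" -> list(het=69); bare name
.parse_token <- function(tok) {
  tok <- .strip_token(tok)
  if (grepl("^h[0-9]+$", tok))
    return(list(type = "het", frac = as.numeric(sub("^h", "", tok))))
  m <- regmatches(tok, regexec("^([A-Za-z]{3})\\(([ACGT]{3})\\)$", tok))[[1]]
  if (length(m) == 3L)
    return(list(type = "codon", aa = m[2], codon = m[3]))
  if (grepl("^[A-Za-z]{3}$", tok))
    return(list(type = "aa", aa = tok))
  NULL
}

.apply_corrections <- function(tok, gene, pos_label, column, corrections,
                               notes_env) {
  hit <- corrections$gene == gene &
    corrections$position == pos_label &
    corrections$column == column &
    corrections$printed == .strip_token(tok)
  if (any(hit)) {
    i <- which(hit)[1]
    notes_env$notes <- c(notes_env$notes, sprintf(
      "correction at %s %s [%s]: '%s' -> '%s' (%s)", gene, pos_label,
      column, corrections$printed[i], corrections$corrected[i],
      corrections$note[i]))
    return(corrections$corrected[i])
  }
  tok
}

#' Load a published gene site table into a site-state matrix
#'
#' Parses a packaged table fixture (dialect: comment header lines
#' `## gene_id=` / `## chromosome=`, then columns `nr`, `position`,
#' `codon`, `amino_acid`, `reference` and one column per sample). Cell
#' token grammar: `hNN` is a heterozygous call with NN% alternate reads;
#' `Xxx(COD)` is a homozygous call identified by its codon; a bare
#' three-letter amino acid is matched against the reference and alternate
#' amino acids (when both match — a silent site printed without codons —
#' the reference state is assumed and noted). Multi-position rows may
#' carry `/`-separated per-position tokens. Effects are recomputed from
#' the codons via [classify_effect()], never trusted from the printed
#' amino-acid column.
#'
#' @param path Path to a fixture TSV (see [bdg_table_paths()]).
#' @param corrections_path Path to the corrections TSV (defaults to the
#'   packaged file); `NULL` disables corrections.
#' @return A `site_state_matrix`: `gene_id`, `chromosome`, `rows`
#'   (data.frame with `position_label`, `ref_codon`, `alt_codons`,
#'   `ref_aa`, `alt_aas`, `effect`, `polarity_change`, `charge_change`),
#'   `positions` (list of integer vectors), `states`/`fracs` (lists of
#'   position x sample matrices), `samples`, `notes`.
#' @export
read_site_table <- function(path, corrections_path = .default_corrections()) {
  if (!file.exists(path)) stop("site table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^##", lines, value = TRUE)
  gene_id <- sub("^##\\s*gene_id=", "", grep("gene_id=", meta, value = TRUE))
  chromosome <- sub("^##\\s*chromosome=", "",
                    grep("chromosome=", meta, value = TRUE))
  if (length(gene_id) != 1L)
    stop("fixture error: missing '## gene_id=' header in ", path)
  df <- utils::read.delim(text = lines[!startsWith(lines, "##")],
                          header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  fixed_cols <- c("nr", "position", "codon", "amino_acid", "reference")
  if (!all(fixed_cols %in% names(df)))
    stop("fixture error: expected columns ", paste(fixed_cols, collapse = ", "))
  samples <- setdiff(names(df), fixed_cols)
  if (length(samples) == 0L) stop("fixture error: no sample columns")

  corrections <- if (is.null(corrections_path)) {
    data.frame(gene = character(0), position = character(0),
               column = character(0), printed = character(0),
               corrected = character(0), note = character(0))
  } else {
    utils::read.delim(corrections_path, header = TRUE, sep = "\t",
                      colClasses = "character")
  }
  env <- new.env(); env$notes <- character(0)

  rows <- list(); states <- list(); fracs <- list(); positions <- list()
  for (r in seq_len(nrow(df))) {
    pos_label <- .strip_token(df$position[r])
    codons <- .strip_token(strsplit(df$codon[r], "/", fixed = TRUE)[[1]])
    if (any(!grepl("^[ACGT]{3}$", codons)))
      stop("fixture error in row ", df$nr[r], ": bad codon field '",
           df$codon[r], "'")
    ref_codon <- codons[1]; alt_codons <- codons[-1]

    # positions: endpoints label; the changed codon offsets give the SNPs
    ends <- as.integer(strsplit(pos_label, "-", fixed = TRUE)[[1]])
    ref_b <- strsplit(ref_codon, "", fixed = TRUE)[[1]]
    changed <- sort(unique(unlist(lapply(alt_codons, function(a)
      which(strsplit(a, "", fixed = TRUE)[[1]] != ref_b)))))
    pos <- if (length(ends) == 1L) ends else ends[1] + changed - 1L
    if (length(ends) > 1L && max(pos) != ends[2])
      env$notes <- c(env$notes, sprintf(
        "row %s: printed range %s inconsistent with %d changed codon offset(s)",
        df$nr[r], pos_label, length(changed)))
    if (length(ends) > 1L) {
      ci <- unique(ceiling(pos / 3))
      if (length(ci) != 1L)
        env$notes <- c(env$notes, sprintf(
          "row %s: positions %s span codons %s by frame arithmetic; printed codons kept",
          df$nr[r], pos_label, paste(ci, collapse = ",")))
    }

    change <- classify_effect(list(ref_codon = ref_codon,
                                   alt_codons = alt_codons))
    aa_col <- .strip_token(gsub("\\(s[Ii]lent\\)", "", df$amino_acid[r]))
    aa_tokens <- strsplit(aa_col, "/", fixed = TRUE)[[1]]
    if (!identical(unname(aa_tokens[1]), change$ref_aa) ||
        !identical(unname(aa_tokens[-1]), unname(change$alt_aas)))
      env$notes <- c(env$notes, sprintf(
        "row %s: printed amino acids '%s' differ from translation %s/%s",
        df$nr[r], df$amino_acid[r], change$ref_aa,
        paste(change$alt_aas, collapse = "/")))

    ref_tok <- .apply_corrections(df$reference[r], gene_id, pos_label,
                                  "reference", corrections, env)
    pr <- .parse_token(ref_tok)
    ok_ref <- !is.null(pr) &&
      ((pr$type == "codon" && pr$codon == ref_codon) ||
       (pr$type == "aa" && pr$aa == change$ref_aa))
    if (!ok_ref)
      stop("fixture error in row ", df$nr[r],
           ": reference cell '", df$reference[r],
           "' does not match reference codon ", ref_codon)

    np <- length(pos)
    st <- matrix(NA_character_, nrow = np, ncol = length(samples))
    fr <- matrix(NA_real_, nrow = np, ncol = length(samples))
    for (j in seq_along(samples)) {
      cell <- .apply_corrections(df[[samples[j]]][r], gene_id, pos_label,
                                 samples[j], corrections, env)
      toks <- strsplit(.strip_token(cell), "/", fixed = TRUE)[[1]]
      if (length(toks) == 1L) toks <- rep(toks, np)
      if (length(toks) != np)
        stop("fixture error in row ", df$nr[r], ", sample ", samples[j],
             ": ", length(toks), " tokens for ", np, " position(s)")
      for (p in seq_len(np)) {
        tk <- .parse_token(toks[p])
        if (is.null(tk))
          stop("fixture error in row ", df$nr[r], ", sample ", samples[j],
               ": unparseable token '", toks[p], "'")
        if (tk$type == "het") {
          if (tk$frac > 100)
            stop("fixture error in row ", df$nr[r], ", sample ", samples[j],
                 ": heterozygous fraction above 100%")
          st[p, j] <- "het"; fr[p, j] <- tk$frac
        } else if (tk$type == "codon") {
          if (tk$codon == ref_codon) { st[p, j] <- "hom_ref"; fr[p, j] <- 0 }
          else if (tk$codon %in% alt_codons) { st[p, j] <- "hom_alt"; fr[p, j] <- 100 }
          else stop("fixture error in row ", df$nr[r], ", sample ",
                    samples[j], ": codon '", tk$codon,
                    "' matches neither reference nor alternate")
        } else {
          is_ref <- tk$aa == change$ref_aa
          is_alt <- tk$aa %in% change$alt_aas
          if (is_ref && is_alt) {
            st[p, j] <- "hom_ref"; fr[p, j] <- 0
            env$notes <- c(env$notes, sprintf(
              "row %s, sample %s: bare token '%s' matches both states; reference assumed",
              df$nr[r], samples[j], tk$aa))
          } else if (is_ref) { st[p, j] <- "hom_ref"; fr[p, j] <- 0 }
          else if (is_alt) { st[p, j] <- "hom_alt"; fr[p, j] <- 100 }
          else stop("fixture error in row ", df$nr[r], ", sample ",
                    samples[j], ": token '", tk$aa,
                    "' matches neither reference nor alternate amino acid")
        }
      }
    }
    colnames(st) <- colnames(fr) <- samples
    rows[[r]] <- data.frame(
      position_label = pos_label, ref_codon = ref_codon,
      alt_codons = paste(alt_codons, collapse = "/"),
      ref_aa = change$ref_aa,
      alt_aas = paste(change$alt_aas, collapse = "/"),
      effect = change$effect,
      polarity_change = change$polarity_change,
      charge_change = change$charge_change,
      stringsAsFactors = FALSE)
    states[[r]] <- st; fracs[[r]] <- fr; positions[[r]] <- pos
  }
  rows <- do.call(rbind, rows)
  if (any(diff(vapply(positions, min, 0)) <= 0))
    stop("fixture error: site positions not strictly increasing")
  structure(list(gene_id = gene_id,
                 chromosome = if (length(chromosome)) chromosome else NA,
                 rows = rows, positions = positions,
                 states = states, fracs = fracs,
                 samples = samples, notes = env$notes),
            class = "site_state_matrix")
}

#' Load all three packaged gene tables
#'
#' @param corrections_path Corrections file (defaults to the packaged one).
#' @return Named list of `site_state_matrix` objects.
#' @export
read_bdg_tables <- function(corrections_path = .default_corrections()) {
  lapply(bdg_table_paths(), read_site_table,
         corrections_path = corrections_path)
}
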