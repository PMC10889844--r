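#' Read a genome FASTA file
#'
#' Parses a (multi-record) FASTA file into a named character vector of
#' uppercase chromosome sequences, in file order. Sequences must use the
#' alphabet `{A,C,G,T,N}` (case-insensitive); anything else is a format
#' error reported with its line number.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) .fasta_diagnose(path, conditionMessage(e)),
    warning = function(w) .fasta_diagnose(path, conditionMessage(w))
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) .fasta_diagnose(path, "empty record name")
  if (anyDuplicated(names(seqs)))
    stop("FASTA format error: duplicate record name '",
         names(seqs)[duplicated(names(seqs))][1], "' in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) .fasta_diagnose(path, "illegal sequence character")
  seqs
}

# Locate the offending line for a malformed FASTA so errors name it.
.fasta_diagnose <- function(path, why) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("FASTA format error in ", path, ": empty file")
  if (!startsWith(trimws(lines[1]), ">"))
    stop("FASTA format error in ", path, " at line 1: expected '>' header")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (!nzchar(sub("^>", "", ln)))
        stop("FASTA format error in ", path, " at line ", i, ": empty header")
    } else if (grepl("[^ACGTNacgtn]", ln)) {
      stop("FASTA format error in ", path, " at line ", i,
           ": illegal character in sequence")
    }
  }
  stop("FASTA format error in ", path, ": ", why)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (bases per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome Named character vector of sequences, as from [read_fasta()].
#' @return Named integer vector of lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

#' Callable base count of a genome
#'
#' Denominator for per-mille heterozygosity rates. By default, ambiguous
#' `N` bases are excluded (the "without Ns" reference length); set
#' `exclude_n = FALSE` to use the total length.
#'
#' @param genome Named character vector of sequences.
#' @param exclude_n Exclude `N` bases from the count?
#' @return Total callable bases (double, to avoid integer overflow on
#'   Gb-scale genomes).
#' @export
callable_bases <- function(genome, exclude_n = TRUE) {
  tot <- sum(as.numeric(nchar(genome)))
  if (!exclude_n) return(tot)
  n_count <- sum(vapply(genome, function(s) nchar(gsub("[^N]", "", s)),
                        numeric(1)))
  tot - n_count
}
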