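#' Standard genetic code, three-letter amino-acid names
#'
#' Named character vector mapping each of the 64 codons to the three-letter
#' abbreviation of the encoded amino acid, with translation stops encoded as
#' `"Stop"`. This is the standard nuclear code (NCBI translation table 1),
#' the code used by all annotated Lycium protein-coding genes handled here.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' codon_table()[["ATG"]]
codon_table <- function() .GENETIC_CODE_3

.GENETIC_CODE_3 <- c(
  TTT = "Phe", TTC = "Phe", TTA = "Leu", TTG = "Leu",
  CTT = "Leu", CTC = "Leu", CTA = "Leu", CTG = "Leu",
  ATT = "Ile", ATC = "Ile", ATA = "Ile", ATG = "Met",
  GTT = "Val", GTC = "Val", GTA = "Val", GTG = "Val",
  TCT = "Ser", TCC = "Ser", TCA = "Ser", TCG = "Ser",
  CCT = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
  ACT = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
  GCT = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
  TAT = "Tyr", TAC = "Tyr", TAA = "Stop", TAG = "Stop",
  CAT = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
  AAT = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
  GAT = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
  TGT = "Cys", TGC = "Cys", TGA = "Stop", TGG = "Trp",
  CGT = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
  AGT = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
  GGT = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly"
)

#' Translate codons
#'
#' @param codons Character vector of length-3 strings over `{A,C,G,T}`
#'   (case-insensitive). Codons containing any other character (e.g. `N`)
#'   translate to `NA`.
#' @return Character vector of three-letter amino acids (`"Stop"` for stop
#'   codons, `NA` for untranslatable codons).
#' @export
#' @examples
#' translate_codons(c("AAA", "CGA"))
translate_codons <- function(codons) {
  codons <- toupper(codons)
  bad <- !is.na(codons) & !grepl("^[ACGT]{3}$", codons)
  out <- unname(.GENETIC_CODE_3[codons])
  out[bad] <- NA_character_
  out
}

#' Amino-acid property partition
#'
#' Total, disjoint partition of the 20 standard amino acids into the four
#' side-chain property classes used for missense annotation: nonpolar,
#' polar (uncharged), basic and acidic.
#'
#' @return Named character vector: three-letter amino acid -> property class.
#' @export
#' @examples
#' amino_acid_properties()[c("Lys", "Glu", "Ser", "Ala")]
amino_acid_properties <- function() .AA_PROPERTIES

.AA_PROPERTIES <- c(
  Gly = "nonpolar", Ala = "nonpolar", Val = "nonpolar", Leu = "nonpolar",
  Ile = "nonpolar", Pro = "nonpolar", Phe = "nonpolar", Met = "nonpolar",
  Trp = "nonpolar",
  Ser = "polar", Thr = "polar", Cys = "polar", Tyr = "polar",
  Asn = "polar", Gln = "polar",
  Lys = "basic", Arg = "basic", His = "basic",
  Asp = "acidic", Glu = "acidic"
)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

complement_bases <- function(b) unname(.COMPLEMENT[toupper(b)])
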