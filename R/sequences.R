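# Low-level sequence helpers: plain character strings on the surface,
# Biostrings underneath.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes for heterozygous base calls (Sanger-of-amplicon)
IUPAC_HET <- c(M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT")

#' Reverse complement of a DNA string
#'
#' @param dna A single DNA string (A/C/G/T/N and IUPAC codes accepted).
#' @return A single string.
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' @noRd
iupac_het_code <- function(a, b) {
  pair <- paste0(sort(c(a, b)), collapse = "")
  code <- names(IUPAC_HET)[match(pair, IUPAC_HET)]
  if (is.na(code)) abort(sprintf("no IUPAC code for pair %s", pair))
  code
}

#' @noRd
iupac_expand <- function(base) {
  if (base %in% DNA_BASES) return(base)
  hit <- IUPAC_HET[[base]]
  if (is.null(hit)) abort(sprintf("unsupported base call '%s'", base))
  strsplit(hit, "")[[1]]
}

# IUPAC nucleotide classes used for restriction-site matching
IUPAC_DNA <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' @noRd
iupac_to_regex <- function(site) {
  chars <- strsplit(toupper(site), "")[[1]]
  paste0(vapply(chars, function(ch) {
    cls <- IUPAC_DNA[[ch]]
    if (is.null(cls)) abort(sprintf("bad IUPAC site character '%s'", ch))
    if (nchar(cls) == 1L) cls else paste0("[", cls, "]")
  }, character(1)), collapse = "")
}

#' Translate an in-frame coding sequence
#'
#' Codons containing N (or any non-ACGT base) translate to X; trailing
#' partial codons are dropped.
#'
#' @param dna A single DNA string.
#' @return Single-letter amino acid string ("*" marks stops).
#' @export
translate_cds <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  codons <- substring(dna, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# standard genetic code as a named lookup (names = codons)
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Six-frame translation
#'
#' Translates a genomic sequence in all six reading frames: +1/+2/+3 on the
#' given strand and -1/-2/-3 on the reverse complement. Frame +k starts at
#' base k; frame -k starts at base k of the reverse complement.
#'
#' @param dna A single DNA string over A/C/G/T/N.
#' @return A tibble with columns `frame` (character, "+1".."-3"), `strand`,
#'   `offset` (0-based), and `peptide`.
#' @export
#' @examples
#' six_frame_translate("ATGAAA")
six_frame_translate <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) < 3L) abort("sequence shorter than one codon")
  dna <- toupper(dna)
  rc <- revcomp(dna)
  frames <- tibble(
    frame  = c("+1", "+2", "+3", "-1", "-2", "-3"),
    strand = rep(c("+", "-"), each = 3L),
    offset = rep(0:2, 2L)
  )
  frames$peptide <- vapply(seq_len(6L), function(i) {
    src <- if (frames$strand[i] == "+") dna else rc
    translate_cds(substr(src, frames$offset[i] + 1L, nchar(src)))
  }, character(1))
  frames
}
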