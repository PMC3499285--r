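# Pairwise alignment and percent identity.
#
# Protein alignments use the Gonnet (1992) substitution scores with affine
# gap penalties (open 7, extend 0.2); nucleotide homology screening uses a
# simple match/mismatch scheme. Dynamic programming is delegated to
# Biostrings::pairwiseAlignment.

#' Gonnet 1992 amino acid substitution matrix
#'
#' @return A 20x20 numeric matrix of log-odds scores.
#' @export
gonnet_matrix <- function() {
  if (is.null(the$gonnet)) {
    m <- as.matrix(utils::read.delim(extdata("gonnet1992.tsv"),
                                     check.names = FALSE))
    rownames(m) <- colnames(m)
    the$gonnet <- m
  }
  the$gonnet
}

#' Optimal global alignment of two peptides
#'
#' Needleman-Wunsch global alignment with affine gap penalties. Defaults
#' match the ClustalW-style parameterization used for defensin
#' prepropeptides: Gonnet scores, gap open 7, gap extension 0.2. A gap run
#' of length k costs open + k * extend. Ties are broken deterministically
#' by the alignment engine.
#'
#' @param a,b Peptide strings (nonempty).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix Substitution score matrix; default [gonnet_matrix()].
#' @param type `"global"` (default) or `"local"`.
#' @return A list of class `defensin_alignment`: `aligned_a`, `aligned_b`
#'   (gapped strings), `score`.
#' @export
#' @examples
#' align_pair("ACDE", "ACE")
align_pair <- function(a, b, gap_open = 7, gap_extend = 0.2,
                       matrix = gonnet_matrix(), type = "global") {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || is.na(a) || is.na(b) || nchar(a) == 0L ||
      nchar(b) == 0L) {
    abort("align_pair() needs two nonempty sequences")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = type)
  structure(list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
                 aligned_b = as.character(Biostrings::alignedSubject(aln)),
                 score = Biostrings::score(aln)),
            class = "defensin_alignment")
}

#' @export
print.defensin_alignment <- function(x, ...) {
  cat("Pairwise alignment (score ", format(x$score), ")\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity between two aligned strings
#'
#' Identity = matching columns / aligned columns x 100, counting internal
#' gap columns in the denominator but excluding terminal gap columns.
#'
#' @param aln_a,aln_b Equal-length gapped strings.
#' @return Percent identity in [0, 100].
#' @export
identity_from_alignment <- function(aln_a, aln_b) {
  ca <- strsplit(aln_a, "")[[1]]
  cb <- strsplit(aln_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  gap <- ca == "-" | cb == "-"
  inner <- which(!gap)
  if (length(inner) == 0L) return(0)
  keep <- seq(min(inner), max(inner))   # drop terminal gap columns
  100 * sum(ca[keep] == cb[keep] & ca[keep] != "-") / length(keep)
}

#' Percent identity between two peptides
#'
#' Aligns globally under [align_pair()] defaults, then applies the declared
#' identity convention (matches / aligned columns, terminal gaps excluded).
#'
#' @inheritParams align_pair
#' @param ... Passed to [align_pair()].
#' @return Percent identity in [0, 100].
#' @export
percent_identity <- function(a, b, ...) {
  aln <- align_pair(a, b, ...)
  identity_from_alignment(aln$aligned_a, aln$aligned_b)
}

#' @noRd
nucleotide_matrix <- function(match = 2, mismatch = -2) {
  bases <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' @noRd
align_dna_local <- function(a, b, gap_open = 5, gap_extend = 2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = nucleotide_matrix(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}
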