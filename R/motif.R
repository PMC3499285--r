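#' Scan a peptide for the beta-defensin six-cysteine motif
#'
#' Beta-defensins carry six cysteines with conserved spacing,
#' C-X6-C-X4-C-X9-C-X6-C-C. The scanner reports every (possibly
#' overlapping) window that satisfies the spacing constraints. Spacer
#' residues may be any amino acid (including X from ambiguous codons);
#' the six anchor positions must be literal C — X never matches C.
#'
#' @param peptide A single peptide string (20-letter alphabet plus X and *).
#' @param spacing A list of five integer pairs giving (min, max) intervening
#'   residues between consecutive cysteines. The default fixes the canonical
#'   spacing (6, 4, 9, 6, 0), giving a 31-residue motif span.
#' @return A tibble with one row per match: `start` (0-based residue offset),
#'   `span` (residues), and `cys_offsets` (list column of the six 0-based
#'   cysteine offsets).
#' @export
#' @examples
#' pep <- paste0("C", strrep("A", 6), "C", strrep("A", 4), "C",
#'               strrep("A", 9), "C", strrep("A", 6), "CC")
#' scan_six_cys_motif(pep)
scan_six_cys_motif <- function(peptide,
                               spacing = list(c(6L, 6L), c(4L, 4L),
                                              c(9L, 9L), c(6L, 6L),
                                              c(0L, 0L))) {
  stopifnot(is.character(peptide), length(peptide) == 1L,
            is.list(spacing), length(spacing) == 5L)
  empty <- tibble(start = integer(), span = integer(),
                  cys_offsets = list())
  if (is.na(peptide) || nchar(peptide) == 0L) return(empty)
  spacers <- vapply(spacing, function(p) {
    stopifnot(length(p) == 2L, p[1] >= 0L, p[2] >= p[1])
    sprintf("(.{%d,%d})", p[1], p[2])
  }, character(1))
  # lookahead so overlapping matches are all reported
  pat <- paste0("(?=(C", spacers[1], "C", spacers[2], "C", spacers[3],
                "C", spacers[4], "C", spacers[5], "C))")
  m <- gregexpr(pat, peptide, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L                       # 0-based
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  rows <- lapply(seq_along(starts), function(i) {
    spans <- cl[i, 2:6]                              # realized spacer lengths
    cys <- integer(6)
    cys[1] <- starts[i]
    for (k in 1:4) cys[k + 1] <- cys[k] + 1L + spans[k]
    cys[6] <- cys[5] + 1L + spans[5]
    tibble(start = starts[i], span = as.integer(cl[i, 1]),
           cys_offsets = list(cys))
  })
  out <- list_rbind(rows)
  arrange(out, .data$start)
}

#' @noRd
has_six_cys_motif <- function(peptide, spacing = NULL) {
  if (is.null(spacing)) {
    grepl("C.{6}C.{4}C.{9}C.{6}CC", peptide)
  } else {
    nrow(scan_six_cys_motif(peptide, spacing)) > 0L
  }
}
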