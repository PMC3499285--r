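# Ortholog-based naming: candidate genes take the number of their nearest
# human reference by percent identity, confirmed against clade membership
# in a bootstrap tree, with the established legacy exceptions retained.

#' @noRd
symbol_number <- function(x) {
  sub("^(DEFB|BBD|pBD)", "", x)
}

#' Assign ortholog-based gene names
#'
#' Each candidate is named `pBD<number>` after the human reference
#' (`DEFB<number>`) with the highest percent identity. When the top two
#' references lie within `tie_tol` identity points the name is flagged
#' ambiguous rather than chosen silently. Candidates listed in the legacy
#' table keep their established names (with the nearest reference recorded
#' as evidence). If a bootstrap tree over candidates and references is
#' supplied, the assignment is checked against clade membership: the name
#' is flagged unconfirmed when the candidate's smallest
#' reference-containing clade does not contain the chosen reference.
#'
#' @param candidates Tibble with columns `id`, `sequence` (peptides), or a
#'   named character vector.
#' @param panel Tibble with columns `id`, `sequence`; ids of human
#'   references must carry the DEFB prefix.
#' @param legacy Legacy exceptions, default [legacy_table()].
#' @param tree Optional `phylo` tree containing candidate and panel tips.
#' @param tie_tol Identity-point tolerance for declaring a tie (default 0.5).
#' @return A tibble: `candidate`, `assigned_name`, `nearest_ref`,
#'   `identity`, `margin`, `ambiguous`, `legacy_kept`, `clade_confirmed`.
#' @export
assign_ortholog_name <- function(candidates, panel, legacy = legacy_table(),
                                 tree = NULL, tie_tol = 0.5) {
  if (is.character(candidates)) {
    candidates <- tibble(id = names(candidates), sequence = candidates)
  }
  human <- filter(panel, startsWith(.data$id, "DEFB"))
  if (nrow(human) == 0L) abort("panel contains no human-named references")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    ids <- vapply(human$sequence, function(s) {
      percent_identity(cand$sequence, s)
    }, numeric(1))
    ord <- order(ids, decreasing = TRUE)
    best <- ord[1]
    margin <- if (length(ids) > 1L) ids[best] - ids[ord[2]] else Inf
    ambiguous <- margin < tie_tol
    nearest <- human$id[best]
    legacy_row <- match(cand$id, legacy$gene)
    legacy_kept <- !is.na(legacy_row) && legacy$keep_name[legacy_row]
    name <- if (legacy_kept) cand$id else {
      if (ambiguous) NA_character_ else
        paste0("pBD", symbol_number(nearest))
    }
    confirmed <- NA
    if (!is.null(tree) && cand$id %in% tree$tip.label) {
      confirmed <- clade_confirms(tree, cand$id, nearest, human$id)
    }
    tibble(candidate = cand$id, assigned_name = name, nearest_ref = nearest,
           identity = ids[best], margin = margin, ambiguous = ambiguous,
           legacy_kept = legacy_kept, clade_confirmed = confirmed)
  })
  list_rbind(rows)
}

# Does the smallest clade containing the candidate and any human reference
# contain the chosen reference?
#' @noRd
clade_confirms <- function(tree, candidate, nearest, human_ids) {
  human_in <- intersect(human_ids, tree$tip.label)
  if (!(nearest %in% tree$tip.label) || length(human_in) == 0L) return(NA)
  tr <- tree
  if (!ape::is.rooted(tr)) {
    out <- setdiff(tr$tip.label, c(candidate, human_in))[1]
    if (is.na(out)) out <- setdiff(human_in, nearest)[1]  # all-human panel
    if (is.na(out)) return(NA)
    tr <- ape::root(tr, outgroup = out, resolve.root = TRUE)
  }
  n_tip <- length(tr$tip.label)
  cand_tip <- match(candidate, tr$tip.label)
  node <- cand_tip
  repeat {
    parent <- tr$edge[tr$edge[, 2] == node, 1]
    if (length(parent) == 0L) return(NA)
    tips <- ape::extract.clade(tr, parent)$tip.label
    if (any(human_in %in% tips)) {
      return(nearest %in% tips)
    }
    node <- parent
    if (node == n_tip + 1L) return(NA)
  }
}
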