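# Neighbor-joining tree construction and bootstrap consensus.
#
# The NJ agglomeration is implemented here (fixed tie-break, explicit
# negative-branch handling); ape supplies the tree container, Newick I/O,
# and the majority-rule consensus machinery.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Saitou & Nei). Ties in the Q criterion are
#' broken deterministically by the lowest (row, column) index pair in the
#' current matrix. Negative branch length estimates are clamped to zero
#' with the deficit transferred to the sibling branch, preserving the
#' joined pair's path length.
#'
#' @param d A symmetric numeric matrix with zero diagonal and row/column
#'   names (or a `dist` object).
#' @return An unrooted `phylo` tree (ape).
#' @export
#' @examples
#' d <- matrix(c(0, 3, 5, 3,  3, 0, 6, 4,
#'               5, 6, 0, 4,  3, 4, 4, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d)
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) >= 2L)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix is not symmetric")
  labels <- rownames(d)
  n <- nrow(d)
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        labels[1], d[1, 2] / 2,
                                        labels[2], d[1, 2] / 2))
    return(tr)
  }
  # grow Newick fragments per active node; robust against numbering schemes
  frags <- labels
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], vi, frags[j], vj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frags <- c(frags[keep], newfrag)
    rownames(D2) <- colnames(D2) <- as.character(seq_len(m - 1L))
    D <- D2
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frags[1], l1, frags[2], l2, frags[3], l3)
  ape::read.tree(text = nwk)
}

#' @noRd
p_distance_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- mat[i, ] %in% AA_ORDER & mat[j, ] %in% AA_ORDER
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
    }
  }
  d
}

#' @noRd
alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  stopifnot(is.character(alignment), !is.null(names(alignment)))
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) abort("aligned sequences differ in length")
  do.call(rbind, setNames(strsplit(alignment, ""), names(alignment)))
}

#' Bootstrap majority-rule consensus NJ tree
#'
#' Resamples alignment columns with replacement, builds an NJ tree per
#' replicate, and returns the majority-rule consensus with per-branch
#' bootstrap support (percent of replicates) as node labels. Branches
#' supported by fewer than `collapse` percent of replicates are collapsed
#' into polytomies. Taxa are ordered canonically (alphabetically) before
#' resampling, so supports do not depend on input order; the resampling
#' stream is indexed by replicate only.
#'
#' @param alignment Named character vector of equal-length aligned peptides,
#'   or a character matrix (taxa x sites).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param collapse Collapse threshold in percent (default 50).
#' @param seed Integer seed (default 42); required for reproducibility.
#' @param dist Distance used per replicate: `"p"` (proportion of differing
#'   ungapped columns; default) or `"jtt"` ([jtt_distance()]).
#' @return A `phylo` tree whose `node.label` holds bootstrap percentages.
#' @export
bootstrap_consensus <- function(alignment, n_reps = 1000, collapse = 50,
                                seed = 42, dist = c("p", "jtt")) {
  dist <- match.arg(dist)
  mat <- alignment_matrix(alignment)
  if (nrow(mat) < 3L) abort("bootstrap consensus needs at least 3 taxa")
  if (ncol(mat) < 2L) abort("alignment has fewer than 2 columns")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  dist_fun <- if (dist == "p") p_distance_matrix else function(m) {
    jtt_distance_matrix(setNames(apply(m, 1, paste0, collapse = ""),
                                 rownames(m)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(mat), replace = TRUE)
    trees[[r]] <- nj_tree(dist_fun(mat[, idx, drop = FALSE]))
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = max(collapse, 50) / 100,
                         check.labels = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- n_reps
  cons$node.label <- as.character(round(100 * counts / n_reps, 1))
  cons
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
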