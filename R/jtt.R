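# JTT (Jones-Taylor-Thornton 1992) amino acid substitution model:
# maximum-likelihood pairwise distances and sequence-pair simulation.

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' JTT rate model components
#'
#' Builds the normalized instantaneous rate matrix Q from the published JTT
#' exchangeabilities and equilibrium frequencies, scaled so the expected
#' substitution rate at equilibrium is 1 per site, together with its
#' symmetric eigendecomposition (used to compute transition matrices
#' P(t) = exp(Qt)).
#'
#' @return A list with `Q`, `pi`, and eigendecomposition pieces.
#' @export
jtt_model <- function() {
  if (!is.null(the$jtt)) return(the$jtt)
  S <- as.matrix(utils::read.delim(extdata("jtt_exchangeabilities.tsv"),
                                   check.names = FALSE))
  rownames(S) <- colnames(S)
  fr <- utils::read.delim(extdata("jtt_frequencies.tsv"))
  pi <- setNames(fr$freq, fr$aa)
  S <- S[AA_ORDER, AA_ORDER]
  pi <- pi[AA_ORDER]
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # D^(1/2) Q D^(-1/2) is symmetric: eigendecompose once, reuse for any t
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  the$jtt <- list(Q = Q, pi = pi,
                  left = diag(1 / d) %*% e$vectors,
                  right = t(e$vectors) %*% diag(d),
                  values = e$values)
  the$jtt
}

#' @noRd
jtt_prob <- function(t, model = jtt_model()) {
  P <- model$left %*% diag(exp(model$values * t)) %*% model$right
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ORDER, AA_ORDER)
  P
}

#' @noRd
aligned_aa_pairs <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    aln <- align_pair(a, b)
    a <- aln$aligned_a; b <- aln$aligned_b
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- ca %in% AA_ORDER & cb %in% AA_ORDER
  list(a = ca[keep], b = cb[keep])
}

#' Maximum-likelihood JTT distance between two peptides
#'
#' Estimates the evolutionary distance (expected substitutions per site)
#' under the JTT model by maximizing the likelihood of the ungapped aligned
#' columns over t, with a one-dimensional bracketed search on
#' [1e-8, `cap`]. Unaligned inputs are first aligned with [align_pair()]
#' defaults; gapped and ambiguous columns are dropped.
#'
#' @param a,b Peptide strings (aligned or unaligned).
#' @param cap Upper bound on the reported distance (default 5).
#' @return Distance in substitutions/site.
#' @export
#' @examples
#' jtt_distance("ACDEFGHIKL", "ACDEFGHIKL")
jtt_distance <- function(a, b, cap = 5) {
  pr <- aligned_aa_pairs(a, b)
  if (length(pr$a) == 0L) {
    abort("no shared ungapped columns; JTT distance undefined")
  }
  if (all(pr$a == pr$b)) return(0)
  model <- jtt_model()
  ia <- match(pr$a, AA_ORDER)
  ib <- match(pr$b, AA_ORDER)
  nll <- function(t) {
    P <- jtt_prob(t, model)
    -sum(log(model$pi[ia] * P[cbind(ia, ib)]))
  }
  opt <- optimize(nll, interval = c(1e-8, cap), tol = 1e-9)
  min(opt$minimum, cap)
}

#' Simulate a peptide pair at a known JTT distance
#'
#' Draws an ancestral sequence from the JTT equilibrium frequencies and
#' evolves one copy for time `distance` (the other copy is the ancestor),
#' giving a pair whose true divergence is known. Used for
#' parameter-recovery checks of [jtt_distance()].
#'
#' @param distance True distance in substitutions/site.
#' @param n_sites Number of sites.
#' @param seed Optional integer seed.
#' @return A list with `a`, `b` (peptide strings) and `distance`.
#' @export
simulate_jtt_pair <- function(distance, n_sites, seed = NULL) {
  stopifnot(distance >= 0, n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  model <- jtt_model()
  anc <- sample(AA_ORDER, n_sites, replace = TRUE, prob = model$pi)
  P <- jtt_prob(distance, model)
  der <- vapply(anc, function(aa) {
    sample(AA_ORDER, 1L, prob = P[aa, ])
  }, character(1))
  list(a = paste0(anc, collapse = ""), b = paste0(der, collapse = ""),
       distance = distance)
}

#' JTT distance matrix for a set of aligned peptides
#'
#' @param seqs Named character vector of equal-length aligned peptides.
#' @param cap Passed to [jtt_distance()].
#' @return A symmetric matrix of substitutions/site with zero diagonal.
#' @export
jtt_distance_matrix <- function(seqs, cap = 5) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- jtt_distance(seqs[[i]], seqs[[j]], cap = cap)
    }
  }
  d
}
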