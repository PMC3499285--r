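# Independent brute-force oracles and small generators used across tests.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_peptide <- function(n, prob_c = 0.05) {
  probs <- rep((1 - prob_c) / 19, 20)
  probs[AA20 == "C"] <- prob_c
  paste0(sample(AA20, n, replace = TRUE, prob = probs), collapse = "")
}

random_dna_str <- function(n) {
  paste0(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")
}

# position-by-position window check for the canonical 6-Cys motif
oracle_motif_starts <- function(pep) {
  chars <- strsplit(pep, "")[[1]]
  n <- length(chars)
  offsets <- c(0, 7, 12, 22, 29, 30)       # 0-based cysteine offsets
  hits <- integer(0)
  if (n < 31) return(hits)
  for (s in 0:(n - 31)) {
    if (all(chars[s + offsets + 1] == "C")) hits <- c(hits, s)
  }
  hits
}

# full-translation diff: apply the alternate allele to the whole sequence,
# translate both, compare peptides
oracle_consequence <- function(ref, pos, minor) {
  alt <- ref
  substr(alt, pos, pos) <- minor
  tr <- function(s) {
    n <- nchar(s) - nchar(s) %% 3
    codons <- substring(s, seq(1, n - 2, 3), seq(3, n, 3))
    paste0(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  if (tr(ref) == tr(alt)) "synonymous" else "nonsynonymous"
}

# expand an IUPAC site to concrete sequences and report all match starts
iupac_classes <- c(A="A",C="C",G="G",T="T",R="AG",Y="CT",S="CG",W="AT",
                   K="GT",M="AC",B="CGT",D="AGT",H="ACT",V="ACG",N="ACGT")
oracle_site_hits <- function(seq, site) {
  site_chars <- strsplit(site, "")[[1]]
  len <- length(site_chars)
  n <- nchar(seq)
  if (n < len) return(integer(0))
  hits <- integer(0)
  for (w in 1:(n - len + 1)) {
    ok <- TRUE
    for (k in seq_len(len)) {
      b <- substr(seq, w + k - 1, w + k - 1)
      if (!grepl(b, iupac_classes[[site_chars[k]]], fixed = TRUE)) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, w)
  }
  hits
}

# digest both allele sequences with every enzyme; differential iff the
# fragment patterns (cut positions) differ
oracle_rflp <- function(flank, snp_offset, major, minor, enzymes) {
  a <- flank; substr(a, snp_offset, snp_offset) <- major
  b <- flank; substr(b, snp_offset, snp_offset) <- minor
  out <- character(0)
  for (i in seq_len(nrow(enzymes))) {
    ha <- oracle_site_hits(a, enzymes$site[i])
    hb <- oracle_site_hits(b, enzymes$site[i])
    if (!identical(ha, hb)) out <- c(out, enzymes$enzyme[i])
  }
  out
}

# naive in-silico PCR scan
oracle_pcr <- function(template, fwd, rev) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  f_hits <- integer(0); r_ends <- integer(0)
  nf <- nchar(fwd); nr <- nchar(rc); nt <- nchar(template)
  for (s in 1:(nt - nf + 1)) {
    if (substr(template, s, s + nf - 1) == fwd) f_hits <- c(f_hits, s)
  }
  for (s in 1:(nt - nr + 1)) {
    if (substr(template, s, s + nr - 1) == rc) r_ends <- c(r_ends, s + nr - 1)
  }
  lens <- integer(0)
  for (s in f_hits) for (e in r_ends) {
    if (e >= s + nf) lens <- c(lens, e - s + 1)
  }
  sort(lens)
}

# exhaustive global alignment enumeration with affine gap costs
# (open + len * ext per gap run); feasible for sequences up to ~6 residues
oracle_align_score <- function(a, b, mat, open = 7, ext = 0.2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {   # gap in b
      cost <- ext + if (prev == "gb") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "gb"))
    }
    if (j <= length(cb)) {   # gap in a
      cost <- ext + if (prev == "ga") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "m")
}

# random additive distance matrix from a random tree's path lengths
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.1, 1))
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

canonical_motif_peptide <- function() {
  paste0("C", strrep("A", 6), "C", strrep("A", 4), "C",
         strrep("A", 9), "C", strrep("A", 6), "CC")
}
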