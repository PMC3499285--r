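# Candidate gene discovery: six-frame ORF scanning for the 6-Cys motif,
# homology screening against a cDNA reference panel at the published
# thresholds, gene-model construction under the GT-AG rule, and candidate
# classification.

#' Find motif-containing candidate ORFs in genomic sequence
#'
#' Translates each contig in all six frames, extracts maximal stop-free
#' stretches, and reports every ORF of at least `min_orf_aa` residues whose
#' translation contains the six-cysteine motif. Coordinates are 1-based
#' inclusive on the forward strand of the contig and map back to the exact
#' genomic substring.
#'
#' @param contigs Named character vector of contig sequences.
#' @param min_orf_aa Minimum ORF length in residues (default 30).
#' @param spacing Motif spacing, passed to [scan_six_cys_motif()]; NULL
#'   uses the canonical fixed spacing.
#' @return A tibble: `contig`, `frame`, `strand`, `start`, `end`,
#'   `peptide`, `n_motifs`, `motif_starts` (list of 0-based offsets within
#'   the ORF peptide).
#' @export
find_candidate_orfs <- function(contigs, min_orf_aa = 30L, spacing = NULL) {
  if (length(contigs) == 0L) abort("no contigs supplied")
  if (is.null(names(contigs))) {
    names(contigs) <- sprintf("contig%02d", seq_along(contigs))
  }
  rows <- list()
  for (cn in names(contigs)) {
    dna <- toupper(contigs[[cn]])
    L <- nchar(dna)
    frames <- six_frame_translate(dna)
    for (i in seq_len(nrow(frames))) {
      pep <- frames$peptide[i]
      orfs <- gregexpr("[^*]+", pep)[[1]]
      if (orfs[1] == -1L) next
      for (k in seq_along(orfs)) {
        len <- attr(orfs, "match.length")[k]
        if (len < min_orf_aa) next
        orf_pep <- substr(pep, orfs[k], orfs[k] + len - 1L)
        hits <- if (is.null(spacing)) scan_six_cys_motif(orf_pep) else
          scan_six_cys_motif(orf_pep, spacing)
        if (nrow(hits) == 0L) next
        s0 <- orfs[k] - 1L                # 0-based residue offset in frame
        e0 <- s0 + len - 1L
        off <- frames$offset[i]
        if (frames$strand[i] == "+") {
          gs <- off + 3L * s0 + 1L
          ge <- off + 3L * (e0 + 1L)
        } else {
          gs <- L - off - 3L * (e0 + 1L) + 1L
          ge <- L - off - 3L * s0
        }
        rows[[length(rows) + 1L]] <- tibble(
          contig = cn, frame = frames$frame[i], strand = frames$strand[i],
          start = gs, end = ge, peptide = orf_pep,
          n_motifs = nrow(hits), motif_starts = list(hits$start))
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(contig = character(), frame = character(),
                  strand = character(), start = integer(), end = integer(),
                  peptide = character(), n_motifs = integer(),
                  motif_starts = list()))
  }
  arrange(list_rbind(rows), .data$contig, .data$start)
}

#' Homology screen against a cDNA reference panel
#'
#' Local nucleotide alignment of a candidate sequence against every panel
#' entry. Identity is matches / aligned columns (gaps counted, terminal
#' gaps excluded); coverage is the percent of the query aligned. Status
#' follows the published thresholds: `pass` when identity > `min_identity`
#' and coverage > `min_coverage` (strict inequalities), `rescued` when
#' coverage <= `min_coverage` but identity >= `rescue_identity` (the
#' published low-coverage/high-identity inclusions), otherwise `fail`.
#'
#' @param query Candidate nucleotide sequence.
#' @param panel Tibble with columns `id`, `sequence` (nonempty).
#' @param min_identity,min_coverage,rescue_identity Percent thresholds.
#' @param query_id Label for the query in the output.
#' @return A tibble of hits sorted by identity (descending).
#' @export
homology_screen <- function(query, panel, min_identity = 70,
                            min_coverage = 50, rescue_identity = 80,
                            query_id = "query") {
  if (!is.character(query) || length(query) != 1L || nchar(query) == 0L) {
    abort("query must be a single nonempty sequence")
  }
  if (is.null(panel) || nrow(panel) == 0L) {
    abort("reference panel is empty")
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    aln <- align_dna_local(query, panel$sequence[i])
    ident <- identity_from_alignment(aln$aligned_a, aln$aligned_b)
    aligned_q <- sum(strsplit(aln$aligned_a, "")[[1]] != "-")
    cov <- 100 * aligned_q / nchar(query)
    tibble(query = query_id, reference = panel$id[i],
           identity = ident, coverage = cov, score = aln$score)
  })
  hits <- list_rbind(rows)
  hits$status <- dplyr::case_when(
    hits$identity > min_identity & hits$coverage > min_coverage ~ "pass",
    hits$coverage <= min_coverage &
      hits$identity >= rescue_identity ~ "rescued",
    .default = "fail")
  arrange(hits, desc(.data$identity))
}

#' @noRd
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- strsplit(substr(a, 1L, n), "")[[1]]
  cb <- strsplit(substr(b, 1L, n), "")[[1]]
  neq <- which(ca != cb)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# capped common prefix of region[gpos..] vs cdna[cpos..]
#' @noRd
cp_capped <- function(region, gpos, cdna, cpos, cap = 200L) {
  common_prefix_len(substr(region, gpos, gpos + cap - 1L),
                    substr(cdna, cpos, cpos + cap - 1L))
}

# Chain a guide cDNA through a genomic region as co-linear exact-match
# exons separated by GT..AG introns within bounds. Returns exon coordinates
# (region-relative, 1-based) or NULL.
#' @noRd
chain_guided <- function(region, cdna, bounds, backtrack = 6L) {
  k <- min(15L, nchar(cdna))
  seed_hits <- Biostrings::start(
    Biostrings::matchPattern(substr(cdna, 1L, k), Biostrings::DNAString(region)))
  ag_pos <- gregexpr("AG", region, fixed = TRUE)[[1]]
  if (ag_pos[1] == -1L) ag_pos <- integer()
  extend <- function(gpos, cpos, depth = 0L) {
    if (depth > 8L) return(NULL)
    m <- common_prefix_len(substr(region, gpos, nchar(region)),
                           substr(cdna, cpos, nchar(cdna)))
    if (m == 0L) return(NULL)
    if (cpos + m - 1L == nchar(cdna)) {
      return(list(tibble(start = gpos, end = gpos + m - 1L)))
    }
    # the true exon boundary may lie a few bases left of the maximal match
    for (e in seq(m, max(1L, m - backtrack))) {
      donor <- gpos + e
      if (substr(region, donor, donor + 1L) != "GT") next
      acc <- ag_pos[ag_pos - donor + 2L >= bounds[1] &
                      ag_pos - donor + 2L <= bounds[2]]
      if (length(acc) == 0L) next
      rem <- nchar(cdna) - (cpos + e) + 1L
      # rank acceptors by how far the cDNA match extends past them, so the
      # true junction beats coincidental micro-matches inside introns
      ext <- vapply(acc, function(a) {
        cp_capped(region, a + 2L, cdna, cpos + e)
      }, integer(1))
      for (k in order(-ext, acc)) {
        if (ext[k] < min(4L, rem)) break    # sorted descending
        rest <- extend(acc[k] + 2L, cpos + e, depth + 1L)
        if (!is.null(rest)) {
          return(c(list(tibble(start = gpos, end = gpos + e - 1L)), rest))
        }
      }
    }
    NULL
  }
  for (s in seed_hits) {
    res <- extend(s, 1L)
    if (!is.null(res)) return(list_rbind(res))
  }
  NULL
}

# Unguided single-intron model: enumerate GT donors / AG acceptors around
# the motif ORF, keep the junction pair whose spliced sequence yields the
# longest ATG-initiated motif-containing ORF.
#' @noRd
chain_unguided <- function(region, bounds, min_orf_aa = 30L) {
  orfs <- find_candidate_orfs(setNames(region, "r"), min_orf_aa)
  orfs <- filter(orfs, .data$strand == "+")
  if (nrow(orfs) == 0L) return(NULL)
  orf <- orfs[1L, ]
  gt <- gregexpr("GT", region, fixed = TRUE)[[1]]
  ag <- gregexpr("AG", region, fixed = TRUE)[[1]]
  if (gt[1] == -1L || ag[1] == -1L) return(NULL)
  acc_end <- ag + 1L                       # last base of intron
  acc_ok <- acc_end[acc_end >= orf$start - 150L & acc_end < orf$end]
  best <- NULL
  best_len <- -1L
  for (a in sort(acc_ok)) {
    don <- gt[gt >= a + 1L - bounds[2] & gt <= a + 1L - bounds[1]]
    for (d in sort(don)) {
      spliced <- paste0(substr(region, 1L, d - 1L),
                        substr(region, a + 1L, nchar(region)))
      atgs <- gregexpr("ATG", spliced, fixed = TRUE)[[1]]
      if (atgs[1] == -1L) next
      for (m in atgs[atgs <= d - 1L]) {
        pep_full <- translate_cds(substr(spliced, m, nchar(spliced)))
        stop_at <- regexpr("*", pep_full, fixed = TRUE)
        if (stop_at == -1L) next
        pep <- substr(pep_full, 1L, stop_at - 1L)
        if (!has_six_cys_motif(pep)) next
        if (nchar(pep) > best_len) {
          best_len <- nchar(pep)
          cds_len <- 3L * (stop_at)           # incl. stop codon
          exon1_len <- d - m
          best <- tibble(start = c(m, a + 1L),
                         end = c(d - 1L, a + cds_len - exon1_len))
        }
      }
    }
  }
  best
}

#' Build a gene model under the GT-AG rule
#'
#' With a guide cDNA, exons are the co-linear exact-match blocks whose gaps
#' are GT..AG introns within `intron_bounds` (the cDNA-guided boundary
#' determination); without a guide, donor/acceptor pairs are enumerated and
#' the junction set maximizing the ATG-initiated motif-containing ORF is
#' chosen. Regions with no GT..AG-consistent model are classified
#' `rejected` with the reason recorded.
#'
#' @param region Genomic region sequence, oriented so the gene reads
#'   left-to-right (pass the reverse complement for minus-strand loci).
#' @param guide_cdna Optional coding cDNA of the locus.
#' @param intron_bounds Intron length bounds in bp (default 60-10000).
#' @param contig,region_start,strand Provenance used to express exon
#'   coordinates on the forward strand of the source contig:
#'   `region_start` is the contig position of region base 1 (plus strand)
#'   or of the region's last base (minus strand, where region is the
#'   reverse complement of the contig slice ending there... see Details).
#' @details For `strand == "-"`, `region_start` must be the contig
#'   coordinate corresponding to the *last* base of `region` (i.e. the
#'   start of the contig slice that was reverse complemented), and
#'   `region_end` its first base.
#' @param region_end Contig coordinate of the region's first base when
#'   `strand == "-"` (ignored on the plus strand).
#' @return A one-row tibble gene model: `contig`, `strand`, `class`,
#'   `n_exons`, `exons` (list of 1-based inclusive contig coordinates,
#'   ascending), `cdna`, `peptide`, `has_exon1`, `reason`.
#' @export
build_gene_model <- function(region, guide_cdna = NULL,
                             intron_bounds = c(60L, 10000L),
                             contig = NA_character_, region_start = 1L,
                             strand = "+", region_end = NA_integer_) {
  stopifnot(is.character(region), length(region) == 1L)
  exons_rel <- NULL
  reason <- NA_character_
  if (!is.null(guide_cdna)) {
    exons_rel <- chain_guided(region, guide_cdna, intron_bounds)
    if (is.null(exons_rel)) {
      reason <- "non-canonical splice"   # no GT..AG-consistent chain
    }
  } else {
    exons_rel <- chain_unguided(region, intron_bounds)
    if (is.null(exons_rel)) reason <- "no GT-AG-consistent junction set"
  }
  if (is.null(exons_rel)) {
    return(tibble(contig = contig, strand = strand, class = "rejected",
                  n_exons = 0L, exons = list(tibble(start = integer(),
                                                    end = integer())),
                  cdna = NA_character_, peptide = NA_character_,
                  has_exon1 = FALSE, reason = reason))
  }
  cdna <- paste0(substring(region, exons_rel$start, exons_rel$end),
                 collapse = "")
  peptide <- sub("\\*$", "", translate_cds(cdna))
  has_exon1 <- startsWith(cdna, "ATG") && nrow(exons_rel) >= 2L
  if (strand == "+") {
    exons_abs <- tibble(start = region_start + exons_rel$start - 1L,
                        end = region_start + exons_rel$end - 1L)
  } else {
    if (is.na(region_end)) abort("region_end required for minus strand")
    exons_abs <- tibble(start = region_end - exons_rel$end + 1L,
                        end = region_end - exons_rel$start + 1L)
    exons_abs <- arrange(exons_abs, .data$start)
  }
  model <- tibble(contig = contig, strand = strand, class = NA_character_,
                  n_exons = nrow(exons_rel), exons = list(exons_abs),
                  cdna = cdna, peptide = peptide, has_exon1 = has_exon1,
                  reason = NA_character_)
  model$class <- classify_candidate(model)
  model
}

#' Classify a built gene model
#'
#' `intact` for a full exon set translating without internal stop and
#' containing the motif; `three_exon` for the three-exon variant of an
#' otherwise intact model; `partial_psi` when exon 1 is absent;
#' `rejected` otherwise.
#'
#' @param model One-row gene model tibble (see [build_gene_model()]).
#' @return Classification string.
#' @export
classify_candidate <- function(model) {
  stopifnot(nrow(model) == 1L)
  if (model$n_exons == 0L || is.na(model$peptide)) return("rejected")
  internal_stop <- grepl("\\*", model$peptide)
  motif <- has_six_cys_motif(model$peptide)
  if (!model$has_exon1) {
    if (motif && !internal_stop) return("partial_psi")
    return("rejected")
  }
  if (internal_stop || !motif) return("rejected")
  if (model$n_exons == 3L) return("three_exon")
  "intact"
}

#' Discover defensin genes in contigs
#'
#' End-to-end discovery: motif-constrained ORF scan, homology screen of
#' each candidate against the panel (candidates failing both the pass and
#' rescue rules are dropped), then gene-model construction — guided by the
#' best-matching guide cDNA when `guides` are supplied, otherwise by
#' GT-AG junction enumeration — and classification.
#'
#' @inheritParams find_candidate_orfs
#' @inheritParams homology_screen
#' @param contigs Named character vector of contigs.
#' @param panel Reference panel tibble (`id`, `sequence`).
#' @param guides Optional named character vector of guide cDNAs (e.g.
#'   available cDNA/EST sequences).
#' @param intron_bounds Intron length bounds (bp).
#' @return A list with `candidates`, `hits`, and `models` tibbles.
#' @export
discover_genes <- function(contigs, panel, guides = NULL,
                           min_identity = 70, min_coverage = 50,
                           rescue_identity = 80, min_orf_aa = 30L,
                           intron_bounds = c(60L, 10000L), spacing = NULL) {
  candidates <- find_candidate_orfs(contigs, min_orf_aa, spacing)
  hits_all <- list()
  models <- list()
  if (nrow(candidates) > 0L) {
    for (i in seq_len(nrow(candidates))) {
      cand <- candidates[i, ]
      contig_seq <- contigs[[cand$contig]]
      query <- substr(contig_seq, cand$start, cand$end)
      if (cand$strand == "-") query <- revcomp(query)
      hits <- homology_screen(query, panel, min_identity, min_coverage,
                              rescue_identity,
                              query_id = sprintf("%s:%d-%d%s", cand$contig,
                                                 cand$start, cand$end,
                                                 cand$strand))
      hits_all[[i]] <- hits
      if (!any(hits$status %in% c("pass", "rescued"))) next
      pad <- intron_bounds[2] + 3000L
      win_s <- max(1L, cand$start - pad)
      win_e <- min(nchar(contig_seq), cand$end + pad)
      region <- substr(contig_seq, win_s, win_e)
      if (cand$strand == "-") region <- revcomp(region)
      guide <- NULL
      if (!is.null(guides) && length(guides) > 0L) {
        sc <- vapply(guides, function(g) align_dna_local(query, g)$score,
                     numeric(1))
        guide <- guides[[which.max(sc)]]
      }
      models[[length(models) + 1L]] <- build_gene_model(
        region, guide_cdna = guide, intron_bounds = intron_bounds,
        contig = cand$contig,
        region_start = if (cand$strand == "+") win_s else win_s,
        strand = cand$strand,
        region_end = if (cand$strand == "-") win_e else NA_integer_)
    }
  }
  hits <- if (length(hits_all)) list_rbind(hits_all) else
    tibble(query = character(), reference = character(),
           identity = numeric(), coverage = numeric(), score = numeric(),
           status = character())
  models <- if (length(models)) {
    m <- list_rbind(models)
    m$span_start <- map_int(m$exons, ~ if (nrow(.x)) min(.x$start) else NA_integer_)
    m$span_end <- map_int(m$exons, ~ if (nrow(.x)) max(.x$end) else NA_integer_)
    distinct(m, .data$contig, .data$strand, .data$span_start,
             .data$span_end, .keep_all = TRUE)
  } else {
    tibble(contig = character(), strand = character(), class = character(),
           n_exons = integer(), exons = list(), cdna = character(),
           peptide = character(), has_exon1 = logical(),
           reason = character(), span_start = integer(),
           span_end = integer())
  }
  list(candidates = candidates, hits = hits, models = models)
}
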