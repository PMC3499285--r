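# Coding-SNP characterization in exon-2 amplicons: column-wise variant
# calling from per-animal Sanger-style sequences (heterozygotes as IUPAC
# codes), codon consequence annotation at frame offset 0, folded minor
# allele frequencies, differential PCR-RFLP assay design, and in-silico
# PCR.

#' Call SNPs from per-animal exon-2 sequences
#'
#' Compares every animal's amplicon sequence to the reference column by
#' column. Heterozygous IUPAC base calls contribute one chromosome of each
#' allele; homozygous calls contribute two. One record is emitted per
#' biallelic polymorphic column; columns with three or more alleles are
#' flagged (available via `attr(, "flagged")`) and excluded.
#'
#' @param sequences Tibble with columns `animal`, `sequence`, or a
#'   character vector; all sequences must match the reference length.
#' @param reference Exon-2 coding reference sequence (frame offset 0).
#' @param gene Gene label attached to the records.
#' @return A tibble of class `snp_calls`: `gene`, `position`, `major`,
#'   `minor`, `ac_major`, `ac_minor`, `n_chromosomes`, `maf_obs`, with
#'   `consequence`, `aa_major`, `aa_minor` left NA for
#'   [annotate_consequence()].
#' @export
call_snps <- function(sequences, reference, gene = NA_character_) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  stopifnot(length(sequences) >= 1L)
  if (any(nchar(sequences) != nchar(reference))) {
    abort("sequence length differs from reference; supply aligned amplicons")
  }
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  ref <- strsplit(toupper(reference), "")[[1]]
  empty <- tibble(gene = character(), position = integer(),
                  major = character(), minor = character(),
                  ac_major = integer(), ac_minor = integer(),
                  n_chromosomes = integer(), maf_obs = numeric(),
                  consequence = character(), aa_major = character(),
                  aa_minor = character())
  records <- list()
  flagged <- list()
  poly <- which(vapply(seq_along(ref), function(j) {
    any(mat[, j] != ref[j])
  }, logical(1)))
  for (j in poly) {
    calls <- mat[, j]
    chrom <- unlist(lapply(calls, function(b) {
      if (b == "N") return(character(0))          # missing call
      rep(iupac_expand(b), 2L)[1:2]
    }))
    if (length(chrom) == 0L) next
    counts <- sort(table(chrom), decreasing = TRUE)
    if (length(counts) == 1L) next            # het codes may still collapse
    if (length(counts) > 2L) {
      flagged[[length(flagged) + 1L]] <- tibble(
        gene = gene, position = j,
        alleles = paste(names(counts), collapse = "/"))
      next
    }
    # major by count; tie broken in favor of the reference base
    if (counts[1] == counts[2] && names(counts)[2] == ref[j]) {
      counts <- counts[c(2L, 1L)]
    }
    records[[length(records) + 1L]] <- tibble(
      gene = gene, position = j,
      major = names(counts)[1], minor = names(counts)[2],
      ac_major = as.integer(counts[1]), ac_minor = as.integer(counts[2]),
      n_chromosomes = length(chrom),
      maf_obs = as.integer(counts[2]) / length(chrom),
      consequence = NA_character_, aa_major = NA_character_,
      aa_minor = NA_character_)
  }
  out <- if (length(records)) list_rbind(records) else empty
  attr(out, "flagged") <- if (length(flagged)) list_rbind(flagged) else
    tibble(gene = character(), position = integer(), alleles = character())
  class(out) <- c("snp_calls", class(out))
  out
}

#' Annotate codon consequences of called SNPs
#'
#' Positions are 1-based within the exon-2 coding frame at frame offset 0:
#' position p lies in codon ceiling(p / 3) at codon position
#' ((p - 1) mod 3) + 1. The reference and alternate codons are translated
#' and the record marked synonymous or nonsynonymous.
#'
#' @param records SNP records from [call_snps()].
#' @param references Named character vector, gene -> exon-2 coding
#'   sequence (or a single sequence when all records share one gene).
#' @return The records with `consequence`, `aa_major`, `aa_minor` filled.
#' @export
annotate_consequence <- function(records, references) {
  if (nrow(records) == 0L) return(records)
  if (is.null(names(references)) && length(references) == 1L) {
    references <- setNames(rep(references, 1L), records$gene[1])
  }
  for (i in seq_len(nrow(records))) {
    ref <- references[[records$gene[i]]]
    if (is.null(ref)) abort(sprintf("no reference for gene %s",
                                    records$gene[i]))
    p <- records$position[i]
    if (p > nchar(ref) - nchar(ref) %% 3L) {
      abort("SNP position beyond the coding length")
    }
    ci <- ceiling(p / 3)
    cp <- (p - 1L) %% 3L + 1L
    codon <- substr(ref, 3L * ci - 2L, 3L * ci)
    ref_base <- substr(codon, cp, cp)
    # major/minor are frequency-ranked; near MAF 0.5 the reference allele
    # can be the realized minor, so orient the codon swap by the reference
    alt_base <- if (ref_base == records$major[i]) records$minor[i] else
      if (ref_base == records$minor[i]) records$major[i] else {
        warn(sprintf("reference base at %s:%d matches neither allele",
                     records$gene[i], p))
        records$minor[i]
      }
    alt <- codon
    substr(alt, cp, cp) <- alt_base
    aa_ref <- GENETIC_CODE_TABLE[[codon]]
    aa_alt <- GENETIC_CODE_TABLE[[alt]]
    records$aa_major[i] <- aa_ref
    records$aa_minor[i] <- aa_alt
    records$consequence[i] <- if (aa_ref == aa_alt) "synonymous" else
      "nonsynonymous"
  }
  records
}

#' Estimate the minor allele frequency from diploid genotypes
#'
#' Counts the less frequent allele over non-missing chromosomes; the
#' frequency is folded so it never exceeds 0.5 and is invariant under
#' allele relabeling.
#'
#' @param genotypes Vector of per-animal genotypes: minor-allele dosages
#'   (0/1/2), or strings "AA"/"Aa"/"aa"; NA = missing.
#' @return A list with `maf` and `n_chromosomes`.
#' @export
#' @examples
#' estimate_maf(c(0, 1, 2))   # 3 animals AA, Aa, aa -> 0.5
estimate_maf <- function(genotypes) {
  if (is.character(genotypes)) {
    genotypes <- vapply(genotypes, function(g) {
      if (is.na(g)) return(NA_integer_)
      sum(strsplit(g, "")[[1]] == "a")
    }, integer(1))
  }
  genotypes <- genotypes[!is.na(genotypes)]
  if (length(genotypes) == 0L) abort("all genotypes missing; MAF undefined")
  stopifnot(all(genotypes %in% 0:2))
  n_chrom <- 2L * length(genotypes)
  count_a <- sum(genotypes)
  maf <- min(count_a, n_chrom - count_a) / n_chrom
  list(maf = maf, n_chromosomes = n_chrom)
}

#' Design differential PCR-RFLP assays for a SNP
#'
#' Scans every recognition-site window overlapping the SNP in both allele
#' versions of the flanking sequence (IUPAC-expanded matching). An assay
#' is reported when the two alleles' site positions differ — digestion
#' then yields different fragment patterns, equivalently a brute-force
#' double digest distinguishes the alleles. In the typical case exactly
#' one allele carries a site; site positions shifted between alleles also
#' qualify, while a site present identically in both (e.g. a SNP at the W
#' of CCWGG) does not.
#'
#' @param flank Sequence containing the SNP (major allele).
#' @param snp_offset 1-based position of the SNP within `flank`.
#' @param major,minor SNP alleles.
#' @param enzymes Enzyme tibble (`enzyme`, `site`), default [enzyme_table()].
#' @return A tibble: `enzyme`, `site`, `cutting_allele`, `site_pos`
#'   (1-based window starts within the flank, comma-separated).
#' @export
#' @examples
#' design_rflp_assay("TTTGATATCTTT", 7, "A", "G")   # EcoRV cuts allele A
design_rflp_assay <- function(flank, snp_offset, major, minor,
                              enzymes = enzyme_table()) {
  stopifnot(snp_offset >= 1L, snp_offset <= nchar(flank))
  max_site <- max(nchar(enzymes$site))
  if (snp_offset < max_site || nchar(flank) - snp_offset < max_site - 1L) {
    abort("flank too short: need SNP +/- longest recognition site - 1")
  }
  seq_major <- flank
  substr(seq_major, snp_offset, snp_offset) <- major
  seq_minor <- flank
  substr(seq_minor, snp_offset, snp_offset) <- minor
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    site <- enzymes$site[i]
    len <- nchar(site)
    pat <- iupac_to_regex(site)
    wins <- seq(snp_offset - len + 1L, snp_offset)
    hit_major <- wins[vapply(wins, function(w) {
      grepl(pat, substr(seq_major, w, w + len - 1L))
    }, logical(1))]
    hit_minor <- wins[vapply(wins, function(w) {
      grepl(pat, substr(seq_minor, w, w + len - 1L))
    }, logical(1))]
    if (identical(hit_major, hit_minor)) next
    only_major <- setdiff(hit_major, hit_minor)
    cutting <- if (length(only_major) > 0L) major else minor
    pos <- if (length(only_major) > 0L) only_major else
      setdiff(hit_minor, hit_major)
    rows[[length(rows) + 1L]] <- tibble(
      enzyme = enzymes$enzyme[i], site = site, cutting_allele = cutting,
      site_pos = paste(pos, collapse = ","))
  }
  if (length(rows) == 0L) {
    return(tibble(enzyme = character(), site = character(),
                  cutting_allele = character(), site_pos = character()))
  }
  list_rbind(rows)
}

#' In-silico PCR
#'
#' Reports every product where the forward primer matches the plus strand
#' and the reverse complement of the reverse primer matches downstream.
#' Product length runs from the forward primer's 5' end to the reverse
#' primer's 5' end inclusive.
#'
#' @param template Template sequence.
#' @param fwd,rev Primer sequences, 5'->3', at least 15 nt.
#' @param max_mismatch Mismatches tolerated per primer site (default 0).
#' @return A tibble of products sorted by start: `start`, `end`, `length`.
#' @export
insilico_pcr <- function(template, fwd, rev, max_mismatch = 0L) {
  stopifnot(nchar(fwd) >= 15L, nchar(rev) >= 15L)
  tpl <- Biostrings::DNAString(template)
  f_hits <- Biostrings::start(
    Biostrings::matchPattern(fwd, tpl, max.mismatch = max_mismatch))
  r_hits <- Biostrings::end(
    Biostrings::matchPattern(revcomp(rev), tpl,
                             max.mismatch = max_mismatch))
  rows <- list()
  for (s in f_hits) {
    for (e in r_hits) {
      if (e >= s + nchar(fwd)) {
        rows[[length(rows) + 1L]] <- tibble(start = s, end = e,
                                            length = e - s + 1L)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(start = integer(), end = integer(), length = integer()))
  }
  arrange(list_rbind(rows), .data$start, .data$end)
}

#' Genomic vs cDNA amplicon distinguishability
#'
#' Runs [insilico_pcr()] on a genomic template and its spliced cDNA and
#' reports whether the product sizes differ by at least `min_diff` bp
#' (i.e. the primer pair distinguishes the two templates on a gel).
#'
#' @param genomic,cdna Template sequences.
#' @param fwd,rev Primer pair.
#' @param min_diff Minimum resolvable size difference in bp (default 20).
#' @return A tibble with one row per genomic/cDNA product pair:
#'   `genomic_bp`, `cdna_bp`, `diff_bp`, `distinguishable`.
#' @export
pcr_distinguishable <- function(genomic, cdna, fwd, rev, min_diff = 20L) {
  g <- insilico_pcr(genomic, fwd, rev)
  c_ <- insilico_pcr(cdna, fwd, rev)
  if (nrow(g) == 0L || nrow(c_) == 0L) {
    return(tibble(genomic_bp = integer(), cdna_bp = integer(),
                  diff_bp = integer(), distinguishable = logical()))
  }
  out <- tidyr::expand_grid(genomic_bp = g$length, cdna_bp = c_$length)
  mutate(out, diff_bp = abs(.data$genomic_bp - .data$cdna_bp),
         distinguishable = .data$diff_bp >= min_diff)
}

#' Write SNP records as a minimal VCF 4.2 file
#'
#' Positions are 1-based against the per-gene exon-2 local reference; the
#' gene label is carried in INFO. The file carries only the fields the
#' records populate (no genotype columns).
#'
#' @param records Annotated SNP records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(records, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- character(0)
  if (nrow(records) > 0L) {
    maf <- if ("maf" %in% names(records)) records$maf else records$maf_obs
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;CSQ=%s;MAF=%s",
                    records$gene, records$position, records$major,
                    records$minor, records$gene,
                    ifelse(is.na(records$consequence), ".",
                           records$consequence),
                    format(maf, trim = TRUE))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
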