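# Seeded synthetic-data generator: genomes with planted multi-exon defensin
# loci, diverged cDNA reference panels, and diploid populations carrying
# exon-2 SNPs at specified frequencies. Everything downstream is testable
# against the ground truth these functions record.

AMINO_ACIDS <- AA_ORDER
SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Simulation configuration
#'
#' Collects the knobs of the synthetic-genome generator. Defaults mirror
#' the study design being emulated: a divergent reference panel spanning
#' roughly 70-100% identity, 14 discovery animals and 35 genotyped animals.
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig (bp).
#' @param n_planted_genes Total defensin loci planted across contigs.
#' @param intron_length_range Intron length bounds (bp); minimum 4 so the
#'   GT..AG dinucleotides fit.
#' @param panel_divergence_range Per-sequence nucleotide divergence range
#'   for [make_reference_panel()], fractions in [0, 1].
#' @param n_animals Discovery panel size (default 14).
#' @param n_genotyped Genotyping panel size (default 35).
#' @param three_exon_genes How many planted genes get the three-exon
#'   configuration (extra intron inside exon 2).
#' @param psi_genes How many planted genes lack exon 1 (partial psi loci).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42L, n_contigs = 1L,
                              contig_length = 100000L,
                              n_planted_genes = 5L,
                              intron_length_range = c(500L, 2000L),
                              panel_divergence_range = c(0, 0.3),
                              n_animals = 14L, n_genotyped = 35L,
                              three_exon_genes = 0L, psi_genes = 0L) {
  stopifnot(length(intron_length_range) == 2L,
            intron_length_range[1] >= 4L,
            intron_length_range[2] >= intron_length_range[1],
            all(panel_divergence_range >= 0),
            all(panel_divergence_range <= 1),
            n_contigs >= 1L, contig_length >= 1L, n_planted_genes >= 0L,
            three_exon_genes + psi_genes <= n_planted_genes)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 n_planted_genes = as.integer(n_planted_genes),
                 intron_length_range = as.integer(intron_length_range),
                 panel_divergence_range = panel_divergence_range,
                 n_animals = as.integer(n_animals),
                 n_genotyped = as.integer(n_genotyped),
                 three_exon_genes = as.integer(three_exon_genes),
                 psi_genes = as.integer(psi_genes)),
            class = "simulation_config")
}

#' @noRd
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste0(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# background must stay motif-free in all six frames: redraw on the rare hit
#' @noRd
motif_free_dna <- function(n, max_tries = 50L) {
  if (n < 93L) return(random_dna(n))   # too short to hold a motif ORF
  for (k in seq_len(max_tries)) {
    s <- random_dna(n)
    peps <- six_frame_translate(s)$peptide
    if (!any(has_six_cys_motif(peps))) return(s)
  }
  abort("could not draw motif-free background")
}

#' @noRd
random_residues <- function(n, exclude_c = TRUE) {
  pool <- if (exclude_c) setdiff(AMINO_ACIDS, "C") else AMINO_ACIDS
  paste0(sample(pool, n, replace = TRUE), collapse = "")
}

# reverse-translate a peptide through uniformly drawn synonymous codons
#' @noRd
random_codons_for <- function(peptide) {
  aas <- strsplit(peptide, "")[[1]]
  paste0(vapply(aas, function(a) {
    sample(SENSE_CODONS[GENETIC_CODE_TABLE[SENSE_CODONS] == a], 1L)
  }, character(1)), collapse = "")
}

#' @noRd
random_intron <- function(range) {
  len <- sample(seq(range[1], range[2]), 1L)
  paste0("GT", random_dna(len - 4L), "AG")
}

#' @noRd
plant_gene_block <- function(class, intron_range) {
  # mature peptide: flanking residues + one canonical 6-Cys motif; all
  # random residues avoid C so the planted motif is unique. Three-exon loci
  # get a longer leading flank so the extra intron (emulating an insertion
  # upstream of the mature-domain core) leaves the motif intact in one exon.
  lead <- if (class == "three_exon") 10L else 4L
  repeat {
    mature <- paste0(random_residues(lead),
                     "C", random_residues(6L), "C", random_residues(4L),
                     "C", random_residues(9L), "C", random_residues(6L),
                     "CC", random_residues(3L))
    if (nrow(scan_six_cys_motif(mature)) == 1L) break
  }
  signal <- paste0("M", random_residues(18L))
  exon1_cds <- random_codons_for(signal)
  exon2_cds <- paste0(random_codons_for(mature), "TAA")
  if (class == "partial_psi") {
    cdna <- exon2_cds
    parts <- list(exon2_cds)
  } else if (class == "three_exon") {
    cut <- 3L * sample(4:(lead - 2L), 1L)   # within the leading flank
    cdna <- paste0(exon1_cds, exon2_cds)
    parts <- list(exon1_cds, substr(exon2_cds, 1L, cut),
                  substr(exon2_cds, cut + 1L, nchar(exon2_cds)))
  } else {
    cdna <- paste0(exon1_cds, exon2_cds)
    parts <- list(exon1_cds, exon2_cds)
  }
  introns <- replicate(length(parts) - 1L, random_intron(intron_range))
  block <- parts[[1]]
  rel <- tibble(start = 1L, end = nchar(parts[[1]]))
  for (k in seq_along(introns)) {
    s <- nchar(block) + nchar(introns[k]) + 1L
    block <- paste0(block, introns[k], parts[[k + 1L]])
    rel <- bind_rows(rel, tibble(start = s,
                                 end = s + nchar(parts[[k + 1L]]) - 1L))
  }
  peptide <- sub("\\*$", "", translate_cds(cdna))
  list(block = block, exons_rel = rel, cdna = cdna, peptide = peptide,
       mature = mature, class = class)
}

#' Simulate a genome with planted defensin loci
#'
#' Generates uniform-ACGT contigs carrying multi-exon defensin genes with
#' the six-cysteine motif embedded in exon 2 and canonical GT..AG introns,
#' on random strands, at recorded coordinates. Background sequence is
#' rejection-sampled to be motif-free in all six frames, so discovery on a
#' gene-free genome yields no candidates.
#'
#' @param config A [simulation_config()].
#' @return A list with `contigs` (named character vector) and `truth`, a
#'   list holding the planted `genes` tibble (1-based inclusive exon
#'   coordinates, strand, cDNA, prepropeptide, class) and the config.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_planted_genes
  classes <- c(rep("three_exon", config$three_exon_genes),
               rep("partial_psi", config$psi_genes),
               rep("intact", n - config$three_exon_genes - config$psi_genes))
  if (n > 0L) classes <- sample(classes)
  contig_of <- if (n > 0L) rep_len(seq_len(config$n_contigs), n) else integer()
  contigs <- character(config$n_contigs)
  names(contigs) <- sprintf("contig%02d", seq_len(config$n_contigs))
  gene_rows <- list()
  gid <- 0L
  for (ci in seq_len(config$n_contigs)) {
    idx <- which(contig_of == ci)
    blocks <- lapply(classes[idx], plant_gene_block,
                     intron_range = config$intron_length_range)
    total_block <- sum(vapply(blocks, function(b) nchar(b$block), 1L))
    k <- length(blocks)
    margin <- 200L
    bg_total <- config$contig_length - total_block
    if (bg_total < (k + 1L) * margin) {
      abort("contig too short for the requested genes")
    }
    # split background into k+1 segments of random size (>= margin each)
    cuts <- if (k > 0L) {
      sort(sample.int(bg_total - (k + 1L) * margin + 1L, k) - 1L)
    } else integer()
    seg <- diff(c(0L, cuts, bg_total - (k + 1L) * margin)) + margin
    pieces <- character(0)
    offset <- 0L
    for (s in seq_len(k + 1L)) {
      bg <- motif_free_dna(seg[s])
      pieces <- c(pieces, bg)
      offset <- offset + seg[s]
      if (s <= k) {
        b <- blocks[[s]]
        strand <- sample(c("+", "-"), 1L)
        block <- b$block
        exons <- b$exons_rel
        if (strand == "-") {
          block <- revcomp(block)
          bl <- nchar(block)
          exons <- tibble(start = bl - b$exons_rel$end + 1L,
                          end = bl - b$exons_rel$start + 1L)
          exons <- arrange(exons, .data$start)
        }
        gid <- gid + 1L
        gene_rows[[gid]] <- tibble(
          gene_id = sprintf("sBD%03d", gid),
          contig = names(contigs)[ci], strand = strand,
          class = b$class,
          exons = list(mutate(exons, start = .data$start + offset,
                              end = .data$end + offset)),
          start = offset + 1L, end = offset + nchar(block),
          cdna = b$cdna, peptide = b$peptide, mature = b$mature)
        pieces <- c(pieces, block)
        offset <- offset + nchar(block)
      }
    }
    contigs[ci] <- paste0(pieces, collapse = "")
  }
  genes <- if (gid > 0L) list_rbind(gene_rows) else
    tibble(gene_id = character(), contig = character(), strand = character(),
           class = character(), exons = list(), start = integer(),
           end = integer(), cdna = character(), peptide = character(),
           mature = character())
  list(contigs = contigs, truth = list(genes = genes, config = config))
}

#' Simulate a diploid population carrying exon-2 SNPs
#'
#' Each animal's two alleles are drawn binomially at the specified minor
#' allele frequency; the per-animal amplicon sequence reports heterozygous
#' positions as IUPAC ambiguity codes, emulating direct Sanger sequencing
#' of genomic PCR products.
#'
#' @param reference Exon-2 coding reference sequence carrying the major
#'   allele at every SNP position.
#' @param snps A tibble with columns `position` (1-based bp in the exon-2
#'   coding frame), `major`, `minor`, `minor_freq`.
#' @param n_animals Number of diploid animals.
#' @param seed Integer seed.
#' @param ensure_polymorphic If TRUE, force at least one copy of each
#'   allele into the sample (the first animal is made heterozygous when a
#'   site comes out monomorphic).
#' @return A list with `sequences` (tibble: animal, sequence), `genotypes`
#'   (tibble: animal, position, n_minor in 0:2), and `reference`.
#' @export
simulate_population <- function(reference, snps, n_animals, seed = 42L,
                                ensure_polymorphic = FALSE) {
  stopifnot(is.character(reference), length(reference) == 1L,
            all(c("position", "major", "minor", "minor_freq") %in%
                  names(snps)),
            n_animals >= 1L)
  if (any(snps$position < 1L | snps$position > nchar(reference))) {
    abort("SNP position outside the exon-2 coding span")
  }
  if (any(snps$minor_freq < 0 | snps$minor_freq > 0.5)) {
    abort("minor_freq must lie in [0, 0.5]")
  }
  ref_bases <- substring(reference, snps$position, snps$position)
  if (!all(ref_bases == snps$major)) {
    abort("reference does not carry the major allele at every SNP position")
  }
  set.seed(seed)
  geno <- list()
  for (i in seq_len(nrow(snps))) {
    g <- rbinom(n_animals, 2L, snps$minor_freq[i])
    if (ensure_polymorphic) {
      if (all(g == 0L) || all(g == 2L)) g[1L] <- 1L
    }
    geno[[i]] <- tibble(animal = seq_len(n_animals),
                        position = snps$position[i], n_minor = g)
  }
  geno <- list_rbind(geno)
  seqs <- vapply(seq_len(n_animals), function(a) {
    s <- reference
    rows <- filter(geno, .data$animal == a)
    for (i in seq_len(nrow(rows))) {
      j <- match(rows$position[i], snps$position)
      base <- switch(as.character(rows$n_minor[i]),
                     "0" = snps$major[j],
                     "1" = iupac_het_code(snps$major[j], snps$minor[j]),
                     "2" = snps$minor[j])
      substr(s, rows$position[i], rows$position[i]) <- base
    }
    s
  }, character(1))
  list(sequences = tibble(animal = seq_len(n_animals), sequence = seqs),
       genotypes = geno, reference = reference)
}

#' Build a diverged cDNA reference panel from planted genes
#'
#' Applies uniform (Jukes-Cantor-style) nucleotide substitution to each
#' planted gene's cDNA at a per-sequence divergence drawn from
#' `divergence_range`, recording the realized divergence. Recycling the
#' truth genes allows panels larger than the number of planted loci (e.g.
#' a 57-entry panel mirroring the published reference count).
#'
#' @param truth Truth set from [simulate_genome()].
#' @param divergence_range Fraction pair in [0, 1].
#' @param seed Integer seed.
#' @param n_panel Panel size (default: one entry per planted gene).
#' @param ids Optional character vector of panel sequence ids.
#' @return A tibble: `id`, `source_gene`, `target_divergence`,
#'   `realized_divergence`, `sequence`.
#' @export
make_reference_panel <- function(truth, divergence_range = c(0, 0.3),
                                 seed = 42L, n_panel = NULL, ids = NULL) {
  genes <- truth$genes
  if (nrow(genes) == 0L) abort("truth set has no planted genes")
  if (any(divergence_range < 0) || any(divergence_range > 1)) {
    abort("divergence_range must lie in [0, 1]")
  }
  set.seed(seed)
  if (is.null(n_panel)) n_panel <- nrow(genes)
  src <- rep_len(seq_len(nrow(genes)), n_panel)
  rows <- lapply(seq_len(n_panel), function(i) {
    cdna <- genes$cdna[src[i]]
    d <- runif(1L, divergence_range[1], divergence_range[2])
    bases <- strsplit(cdna, "")[[1]]
    hit <- runif(length(bases)) < d
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
    tibble(id = if (is.null(ids)) {
      sprintf("REF%02d_%s", i, genes$gene_id[src[i]])
    } else ids[i],
    source_gene = genes$gene_id[src[i]],
    target_divergence = d,
    realized_divergence = mean(hit),
    sequence = paste0(bases, collapse = ""))
  })
  list_rbind(rows)
}

#' Exon-2 reference sequences consistent with the published SNP table
#'
#' Builds one synthetic exon-2 coding sequence per SNP-carrying gene:
#' random sense codons with the documented codon contexts spliced in at
#' their codon positions, so every published row (position, alleles,
#' amino-acid change, differential restriction site) is reproduced exactly.
#'
#' @param snps SNP fixture (default [snp_table()]).
#' @param seed Integer seed.
#' @param pad_codons Extra codons appended after the last constrained one.
#' @return Named character vector, gene -> exon-2 coding sequence.
#' @export
exon2_reference <- function(snps = snp_table(), seed = 42L,
                            pad_codons = 4L) {
  set.seed(seed)
  genes <- unique(snps$gene)
  out <- setNames(character(length(genes)), genes)
  for (g in genes) {
    rows <- filter(snps, .data$gene == g)
    ctx_end <- max(rows$context_start_codon +
                     nchar(rows$context_seq) %/% 3L - 1L)
    n_codons <- max(ctx_end, ceiling(max(rows$position) / 3L)) + pad_codons
    codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    codons[1L] <- "TGT"  # keep position 1 in frame with a defensin-ish Cys
    for (i in seq_len(nrow(rows))) {
      ctx <- rows$context_seq[i]
      at <- rows$context_start_codon[i]
      ctx_codons <- substring(ctx, seq(1L, nchar(ctx) - 2L, 3L),
                              seq(3L, nchar(ctx), 3L))
      codons[at:(at + length(ctx_codons) - 1L)] <- ctx_codons
    }
    s <- paste0(codons, collapse = "")
    bad <- substring(s, rows$position, rows$position) != rows$major
    if (any(bad)) abort(sprintf("context inconsistent for %s", g))
    out[g] <- s
  }
  out
}

#' Population fixture planting every published exon-2 SNP
#'
#' Builds the per-animal amplicon panel used by the variant-calling stage:
#' for each SNP-carrying gene, a diploid population of `n_animals` with
#' the published alleles at the published positions (both alleles present
#' at each site) at the published minor allele frequencies.
#'
#' @param n_animals Discovery panel size (default 14).
#' @param seed Integer seed.
#' @return A list with `references` (named vector), `populations` (named
#'   list of per-gene outputs of [simulate_population()]), and `snps`
#'   (the fixture rows used).
#' @export
snp_population_fixture <- function(n_animals = 14L, seed = 42L) {
  snps <- snp_table()
  refs <- exon2_reference(snps, seed = seed)
  pops <- lapply(unique(snps$gene), function(g) {
    rows <- filter(snps, .data$gene == g)
    simulate_population(refs[[g]],
                        tibble(position = rows$position,
                               major = rows$major, minor = rows$minor,
                               minor_freq = rows$maf),
                        n_animals = n_animals,
                        seed = seed + match(g, unique(snps$gene)),
                        ensure_polymorphic = TRUE)
  })
  names(pops) <- unique(snps$gene)
  list(references = refs, populations = pops, snps = snps)
}
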