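small_sim <- function(seed = 21, n = 3, ...) {
  cfg <- simulation_config(seed = seed, contig_length = 50000,
                           n_planted_genes = n, ...)
  simulate_genome(cfg)
}

test_that("candidate ORF coordinates map back to the exact genomic substring", {
  sim <- small_sim()
  cands <- find_candidate_orfs(sim$contigs)
  expect_gt(nrow(cands), 0)
  for (i in seq_len(nrow(cands))) {
    sub <- substr(sim$contigs[[cands$contig[i]]], cands$start[i],
                  cands$end[i])
    if (cands$strand[i] == "-") sub <- revcomp(sub)
    expect_equal(translate_cds(sub), cands$peptide[i])
  }
})

test_that("planted loci are recovered as candidates on both strands", {
  sim <- small_sim(seed = 22, n = 4)
  cands <- find_candidate_orfs(sim$contigs)
  genes <- sim$truth$genes
  for (i in seq_len(nrow(genes))) {
    ex2 <- genes$exons[[i]]
    # the motif-bearing exon must be inside one reported candidate ORF
    motif_exon <- if (genes$strand[i] == "+") ex2[nrow(ex2), ] else ex2[1, ]
    hit <- cands$contig == genes$contig[i] &
      cands$strand == genes$strand[i] &
      cands$start <= motif_exon$end & cands$end >= motif_exon$start
    expect_true(any(hit), info = genes$gene_id[i])
  }
})

test_that("discovery is strand-symmetric under reverse complement", {
  sim <- small_sim(seed = 23, n = 2)
  contig <- sim$contigs[1]
  L <- nchar(contig)
  fwd <- find_candidate_orfs(contig)
  rev <- find_candidate_orfs(setNames(revcomp(contig), names(contig)))
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- tibble::tibble(start = L - rev$end + 1L,
                             end = L - rev$start + 1L,
                             peptide = rev$peptide)
  mirrored <- dplyr::arrange(mirrored, start)
  expect_equal(mirrored$start, fwd$start)
  expect_equal(mirrored$end, fwd$end)
  expect_setequal(mirrored$peptide, fwd$peptide)
})

test_that("homology thresholds and the rescue rule follow the published criteria", {
  set.seed(24)
  q <- random_dna_str(200)
  panel <- tibble::tibble(id = "ref1", sequence = q)
  hit <- homology_screen(q, panel)
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 100)
  expect_equal(hit$status, "pass")

  # query = exact 5' half of a panel entry: coverage (of query) 100, pass
  half <- substr(q, 1, 100)
  expect_equal(homology_screen(half, panel)$status, "pass")
  # reverse roles: only half the query aligns; coverage sits on the 50
  # boundary and fails the strict >50 pass rule (identity 100 keeps it
  # in the rescue class rather than pass)
  rev_roles <- homology_screen(q, tibble::tibble(id = "h", sequence = half))
  expect_equal(rev_roles$coverage, 50)
  expect_false(rev_roles$status == "pass")

  # low-coverage/high-identity rescue (the 32%/81% style case)
  frag <- substr(q, 1, 64)
  ch <- strsplit(frag, "")[[1]]
  idx <- seq(3, 63, by = 5)
  ch[idx] <- vapply(ch[idx], function(b) {
    sample(setdiff(c("A","C","G","T"), b), 1)
  }, "")
  panel_frag <- tibble::tibble(id = "frag", sequence = paste0(ch, collapse = ""))
  h <- homology_screen(q, panel_frag)
  expect_lte(h$coverage, 50)
  expect_gte(h$identity, 80)
  expect_equal(h$status, "rescued")

  expect_error(homology_screen(q, tibble::tibble(id = character(),
                                                 sequence = character())),
               "empty")
})

test_that("guided model building recovers planted exon coordinates exactly", {
  sim <- small_sim(seed = 25, n = 4, three_exon_genes = 1)
  panel <- make_reference_panel(sim$truth, c(0.05, 0.2), seed = 26)
  disc <- discover_genes(sim$contigs, panel[, c("id", "sequence")],
                         guides = setNames(sim$truth$genes$cdna,
                                           sim$truth$genes$gene_id))
  genes <- sim$truth$genes
  expect_equal(nrow(disc$models), nrow(genes))
  for (i in seq_len(nrow(genes))) {
    te <- genes$exons[[i]]
    hit <- which(disc$models$span_start == min(te$start) &
                   disc$models$contig == genes$contig[i])
    expect_length(hit, 1)
    expect_equal(as.data.frame(disc$models$exons[[hit]]),
                 as.data.frame(te), ignore_attr = TRUE)
    expect_equal(disc$models$class[hit], genes$class[i])
    expect_equal(disc$models$strand[hit], genes$strand[i])
  }
})

test_that("a GC..AG intron violates the GT-AG rule and is rejected", {
  sim <- small_sim(seed = 27, n = 1)
  g <- sim$truth$genes[1, ]
  contig <- sim$contigs[[g$contig]]
  ex <- g$exons[[1]]
  # mutate the donor GT -> GC (on the gene's own strand)
  if (g$strand == "+") {
    pos <- ex$end[1] + 2L
    substr(contig, pos, pos) <- "C"
  } else {
    pos <- ex$start[2] - 2L    # donor is at the right end on minus strand
    substr(contig, pos, pos) <- "G"  # revcomp(GT)=AC -> AG mutates T->C
  }
  region <- substr(contig, max(1, g$start - 500), min(nchar(contig),
                                                      g$end + 500))
  if (g$strand == "-") region <- revcomp(region)
  model <- build_gene_model(region, guide_cdna = g$cdna)
  expect_equal(model$class, "rejected")
  expect_match(model$reason, "splice")
})

test_that("unguided junction choice yields a GT..AG model maximizing the motif ORF", {
  set.seed(28)
  blk <- defmine:::plant_gene_block("intact", c(70L, 90L))
  region <- paste0(random_dna_str(150), blk$block, random_dna_str(150))
  model <- build_gene_model(region, guide_cdna = NULL,
                            intron_bounds = c(60L, 200L))
  expect_equal(model$class, "intact")
  # an ATG-initiated motif ORF at least as long as the planted one
  expect_true(defmine:::has_six_cys_motif(model$peptide))
  expect_gte(nchar(model$peptide), nchar(blk$cdna) / 3 - 1)
  # the chosen junction obeys the GT-AG rule within bounds
  ex <- model$exons[[1]]
  intron <- substr(region, ex$end[1] + 1L, ex$start[2] - 1L)
  expect_equal(substr(intron, 1, 2), "GT")
  expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
  expect_gte(nchar(intron), 60L)
  expect_lte(nchar(intron), 200L)
})

test_that("classification distinguishes intact, psi, and motif-less models", {
  m <- tibble::tibble(contig = "c", strand = "+", class = NA, n_exons = 2L,
                      exons = list(tibble::tibble(start = 1L, end = 10L)),
                      cdna = "ATG", peptide = canonical_motif_peptide(),
                      has_exon1 = TRUE, reason = NA_character_)
  expect_equal(classify_candidate(m), "intact")
  m3 <- m; m3$n_exons <- 3L
  expect_equal(classify_candidate(m3), "three_exon")
  psi <- m; psi$has_exon1 <- FALSE
  expect_equal(classify_candidate(psi), "partial_psi")
  nomotif <- m; nomotif$peptide <- "MKLV"
  expect_equal(classify_candidate(nomotif), "rejected")
  stopped <- m; stopped$peptide <- paste0("MK*", canonical_motif_peptide())
  expect_equal(classify_candidate(stopped), "rejected")
})

test_that("candidates failing both pass and rescue rules produce no models", {
  sim <- small_sim(seed = 29, n = 1)
  # a panel of unrelated sequence: identity ~50%, coverage low
  set.seed(30)
  panel <- tibble::tibble(id = "junk", sequence = random_dna_str(400))
  disc <- discover_genes(sim$contigs, panel,
                         guides = setNames(sim$truth$genes$cdna,
                                           sim$truth$genes$gene_id))
  expect_equal(nrow(disc$models), 0L)
})
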