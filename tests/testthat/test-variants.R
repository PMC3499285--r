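test_that("a population identical to the reference yields no records", {
  ref <- strrep("ACG", 30)
  out <- call_snps(rep(ref, 14), ref, gene = "g")
  expect_equal(nrow(out), 0L)
})

test_that("the planted fixture reproduces the published SNP table", {
  fix <- snp_population_fixture(n_animals = 14, seed = 1)
  recs <- lapply(names(fix$populations), function(g) {
    annotate_consequence(
      call_snps(fix$populations[[g]]$sequences, fix$references[[g]],
                gene = g),
      fix$references)
  })
  recs <- dplyr::bind_rows(recs)
  expect_equal(nrow(recs), 8L)
  expect_equal(length(unique(recs$gene)), 7L)
  expect_equal(sum(recs$consequence == "nonsynonymous"), 3L)
  expect_setequal(recs$gene[recs$consequence == "nonsynonymous"],
                  c("pBD4", "pBD115", "pBD133"))
  tab <- snp_table()
  key <- paste(recs$gene, recs$position, recs$major, recs$minor)
  expect_setequal(key, paste(tab$gene, tab$position, tab$major, tab$minor))
})

test_that("published codon contexts annotate as printed", {
  fix <- snp_population_fixture(n_animals = 14, seed = 2)
  r <- tibble::tibble(gene = c("pBD4", "pBD115", "pBD1"),
                      position = c(65L, 144L, 171L),
                      major = c("G", "A", "A"), minor = c("A", "T", "G"),
                      ac_major = NA, ac_minor = NA, n_chromosomes = NA,
                      maf_obs = NA, consequence = NA_character_,
                      aa_major = NA_character_, aa_minor = NA_character_)
  ann <- annotate_consequence(r, fix$references)
  # position 65: codon 22, codon position 2, R -> K
  expect_equal(ann$aa_major[1], "R"); expect_equal(ann$aa_minor[1], "K")
  expect_equal(ann$consequence[1], "nonsynonymous")
  # position 144: codon 48 (third position), Q -> H, still nonsynonymous
  expect_equal(ann$aa_major[2], "Q"); expect_equal(ann$aa_minor[2], "H")
  expect_equal(ann$consequence[2], "nonsynonymous")
  # position 171: third codon position, synonymous
  expect_equal(ann$consequence[3], "synonymous")
})

test_that("the synonymous fixture rows all sit at third codon positions", {
  tab <- snp_table()
  syn <- tab[tab$aa_major == "" | is.na(tab$aa_major), ]
  expect_equal(nrow(syn), 5L)
  expect_true(all(syn$position %% 3 == 0))
})

test_that("the caller equals a column-wise comparison oracle, incl. rare alleles", {
  set.seed(55)
  ref <- random_dna_str(120)
  snps <- tibble::tibble(position = c(10L, 50L, 111L),
                         major = substring(ref, c(10, 50, 111),
                                           c(10, 50, 111)),
                         minor = NA_character_, minor_freq = c(0.3, 0.1, 0))
  snps$minor <- vapply(snps$major, function(b) {
    sample(setdiff(c("A","C","G","T"), b), 1)
  }, "")
  snps$minor_freq[3] <- 1 / 28          # single minor chromosome among 14
  pop <- simulate_population(ref, snps, n_animals = 14, seed = 56,
                             ensure_polymorphic = TRUE)
  out <- call_snps(pop$sequences, ref, gene = "g")
  # oracle: expand every column over the 28 chromosomes directly
  truth_counts <- lapply(seq_len(nrow(snps)), function(i) {
    g <- pop$genotypes$n_minor[pop$genotypes$position == snps$position[i]]
    sum(g)
  })
  for (i in seq_len(nrow(snps))) {
    row <- out[out$position == snps$position[i], ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$ac_minor, as.integer(truth_counts[[i]]))
    expect_equal(row$n_chromosomes, 28L)
  }
  expect_equal(nrow(out), 3L)
})

test_that("multi-allelic columns are flagged and excluded", {
  ref <- strrep("ACG", 10)
  seqs <- c(ref, ref, ref)
  substr(seqs[1], 5, 5) <- "A"
  substr(seqs[2], 5, 5) <- "T"
  out <- call_snps(seqs, ref, gene = "g")   # ref C, plus A and T
  expect_false(5 %in% out$position)
  flagged <- attr(out, "flagged")
  expect_equal(flagged$position, 5L)
  expect_match(flagged$alleles, "/.+/")
})

test_that("length mismatches are rejected", {
  expect_error(call_snps(c("ACGT", "ACG"), "ACGT"), "length")
})

test_that("consequence annotation equals the full-translation diff oracle", {
  set.seed(57)
  for (rep in 1:300) {
    n_codons <- sample(10:60, 1)
    ref <- paste0(sample(defmine:::SENSE_CODONS, n_codons, replace = TRUE),
                  collapse = "")
    pos <- sample(nchar(ref), 1)
    major <- substr(ref, pos, pos)
    minor <- sample(setdiff(c("A","C","G","T"), major), 1)
    rec <- tibble::tibble(gene = "g", position = pos, major = major,
                          minor = minor, ac_major = NA, ac_minor = NA,
                          n_chromosomes = NA, maf_obs = NA,
                          consequence = NA_character_,
                          aa_major = NA_character_,
                          aa_minor = NA_character_)
    ann <- annotate_consequence(rec, c(g = ref))
    expect_equal(ann$consequence, oracle_consequence(ref, pos, minor))
  }
})

test_that("positions beyond the coding length raise a coordinate error", {
  rec <- tibble::tibble(gene = "g", position = 7L, major = "A", minor = "G",
                        consequence = NA_character_,
                        aa_major = NA_character_, aa_minor = NA_character_)
  expect_error(annotate_consequence(rec, c(g = "ACGACGA")),  # 7th base off-frame
               "coding length")
})

test_that("MAF estimation counts folded minor alleles over non-missing chromosomes", {
  # 35 animals, 14 minor alleles among 70 chromosomes -> 0.2
  g <- c(rep(1, 14), rep(0, 21))
  est <- estimate_maf(g)
  expect_equal(est$maf, 0.2)
  expect_equal(est$n_chromosomes, 70L)
  expect_equal(estimate_maf(rep(0, 10))$maf, 0)
  expect_equal(estimate_maf(c(0, 1, 2))$maf, 0.5)
  expect_equal(estimate_maf(c("AA", "Aa", "aa"))$maf, 0.5)
  # fold property: relabeling alleles leaves the estimate unchanged
  g2 <- 2 - g
  expect_equal(estimate_maf(g2)$maf, estimate_maf(g)$maf)
  # missing genotypes shrink the denominator
  expect_equal(estimate_maf(c(1, NA, 0))$maf, 0.25)
  expect_error(estimate_maf(c(NA, NA)), "missing")
})

test_that("RFLP design reports a single differential EcoRV assay", {
  flank <- paste0(strrep("T", 10), "GATATC", strrep("T", 10))
  # SNP at the EcoRV 'A' (position 14): A cuts, G does not
  res <- design_rflp_assay(flank, 14, "A", "G")
  eco <- res[res$enzyme == "EcoRV", ]
  expect_equal(nrow(eco), 1L)
  expect_equal(eco$cutting_allele, "A")
  expect_equal(eco$site_pos, "11")
})

test_that("IUPAC degeneracy is honored: CC[A/T]GG never distinguishes BstNI", {
  flank <- paste0(strrep("T", 10), "CCAGG", strrep("T", 10))
  res <- design_rflp_assay(flank, 13, "A", "T")   # W matches both alleles
  expect_false("BstNI" %in% res$enzyme)
  # but an allele completing CCWGG vs one breaking it is distinguishable
  res2 <- design_rflp_assay(flank, 13, "A", "G")
  bst <- res2[res2$enzyme == "BstNI", ]
  expect_equal(nrow(bst), 1L)
  expect_equal(bst$cutting_allele, "A")
})

test_that("assay design equals the brute-force double-digest oracle", {
  set.seed(58)
  enz <- enzyme_table()
  for (rep in 1:150) {
    flank <- random_dna_str(30)
    off <- sample(10:20, 1)
    major <- substr(flank, off, off)
    minor <- sample(setdiff(c("A","C","G","T"), major), 1)
    got <- design_rflp_assay(flank, off, major, minor, enz)$enzyme
    expect_setequal(got, oracle_rflp(flank, off, major, minor, enz))
  }
})

test_that("too-short flanks are rejected", {
  expect_error(design_rflp_assay("ACGTA", 3, "G", "A"), "flank too short")
})

test_that("in-silico PCR product length follows the primer construction", {
  set.seed(59)
  fwd <- random_dna_str(20)
  rev <- random_dna_str(18)
  insert <- random_dna_str(50)
  tpl <- paste0(fwd, insert, revcomp(rev))
  prod <- insilico_pcr(tpl, fwd, rev)
  expect_equal(nrow(prod), 1L)
  expect_equal(prod$length, 20L + 50L + 18L)
  expect_equal(prod$start, 1L)
})

test_that("genomic and spliced templates differ by exactly the intron length", {
  set.seed(60)
  fwd <- random_dna_str(20); rev <- random_dna_str(20)
  left <- random_dna_str(30); right <- random_dna_str(30)
  intron <- paste0("GT", random_dna_str(96), "AG")
  cdna <- paste0(fwd, left, right, revcomp(rev))
  genomic <- paste0(fwd, left, intron, right, revcomp(rev))
  cmp <- pcr_distinguishable(genomic, cdna, fwd, rev)
  expect_equal(cmp$diff_bp, 100L)
  expect_true(cmp$distinguishable)
})

test_that("multiple primer sites give all products, matching the naive scan", {
  set.seed(61)
  fwd <- random_dna_str(16); rev <- random_dna_str(16)
  tpl <- paste0(fwd, random_dna_str(40), revcomp(rev),
                random_dna_str(25), fwd, random_dna_str(10), revcomp(rev))
  prod <- insilico_pcr(tpl, fwd, rev)
  expect_equal(sort(prod$length), oracle_pcr(tpl, fwd, rev))
  expect_equal(prod$start, sort(prod$start))
  expect_gte(nrow(prod), 3L)   # fwd1 pairs with both rev sites
})

test_that("primer mismatch tolerance is honored and short primers rejected", {
  set.seed(62)
  fwd <- random_dna_str(18); rev <- random_dna_str(18)
  tpl <- paste0(fwd, random_dna_str(30), revcomp(rev))
  mut <- fwd
  substr(mut, 9, 9) <- setdiff(c("A","C","G","T"),
                               substr(mut, 9, 9))[1]
  expect_equal(nrow(insilico_pcr(tpl, mut, rev, max_mismatch = 0)), 0L)
  expect_equal(nrow(insilico_pcr(tpl, mut, rev, max_mismatch = 1)), 1L)
  expect_error(insilico_pcr(tpl, "ACGTACG", rev), "15")
})

test_that("VCF output is minimal v4.2 and re-readable", {
  skip_if_not_installed("vcfR")
  fix <- snp_population_fixture(n_animals = 14, seed = 3)
  recs <- lapply(names(fix$populations), function(g) {
    annotate_consequence(
      call_snps(fix$populations[[g]]$sequences, fix$references[[g]],
                gene = g), fix$references)
  })
  recs <- dplyr::bind_rows(recs)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(recs, path)
  expect_equal(readLines(path, n = 1), "##fileformat=VCFv4.2")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), 8L)
  expect_equal(as.integer(v@fix[, "POS"]), recs$position)
})
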