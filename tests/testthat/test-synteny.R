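test_that("the pig coordinate fixture yields the four published clusters", {
  cl <- build_clusters(cluster_positions("pig"), anchor_table())
  expect_equal(nrow(cl), 4L)
  expect_setequal(cl$chromosome, c("SSC7", "SSC14", "SSC15", "SSC17"))
  get_n <- function(chrom) cl$n_members[cl$chromosome == chrom]
  expect_equal(get_n("SSC7"), 5L)
  expect_equal(get_n("SSC14"), 3L)
  expect_equal(get_n("SSC15"), 6L)
  expect_equal(get_n("SSC17"), 12L)
  # anchors label the clusters; SSC17 accepts either upstream candidate
  expect_equal(cl$anchor_down[cl$chromosome == "SSC15"], "SPATA4")
  expect_match(cl$anchor_up[cl$chromosome == "SSC17"], "ZCCHC3|TRIB3")
  # SSC14 is bounded by its own defensin genes
  expect_equal(cl$anchor_up[cl$chromosome == "SSC14"], "pBD135")
  # unplaced genes are reported, never silently placed
  un <- attr(cl, "unplaced")
  expect_true("pBD3" %in% un$gene)
  expect_match(un$note[un$gene == "pBD3"], "SSC15")
})

test_that("cluster membership partitions the placed genes", {
  pos <- cluster_positions("pig")
  cl <- build_clusters(pos, anchor_table())
  members <- unlist(lapply(cl$members, function(m) m$gene))
  placed <- pos$gene[pos$chromosome != "unplaced"]
  expect_setequal(members, placed)
  expect_equal(length(members), length(placed))
})

test_that("the max_gap boundary splits clusters exactly", {
  two <- function(gap) {
    tibble::tibble(species = "sp", gene = c("g1", "g2"), chromosome = "c1",
                   start = c(1000L, 3000L + gap), end = c(2000L, 4000L + gap),
                   strand = "+", note = "")
  }
  max_gap <- 1000
  # gap = start2 - end1
  below <- build_clusters(two(-1L), max_gap = max_gap)   # gap 999
  above <- build_clusters(two(1L), max_gap = max_gap)    # gap 1001
  expect_equal(nrow(below), 1L)
  expect_equal(nrow(above), 2L)
})

test_that("a single gene forms a singleton cluster labeled by itself", {
  pos <- tibble::tibble(species = "sp", gene = "g1", chromosome = "c9",
                        start = 100L, end = 200L, strand = "+", note = "")
  cl <- build_clusters(pos)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 1L)
  expect_equal(cl$label, "g1..g1")
})

test_that("orthologs match by number with legacy mapping; SSC7 matches its human cluster", {
  pig <- build_clusters(cluster_positions("pig"), anchor_table())
  hum <- build_clusters(cluster_positions("human"), anchor_table())
  corr <- match_orthologs_across_species(pig, hum)
  ssc7 <- dplyr::filter(corr$map, cluster_a == "pig_SSC7_1",
                        !is.na(gene_b))
  expect_equal(nrow(ssc7), 5L)             # 133,114,113,4(->110),112
  expect_true("110" %in% ssc7$key)         # legacy pBD4 -> DEFB110
})

test_that("an empty second species leaves every gene unplaced", {
  pig <- build_clusters(cluster_positions("pig"), anchor_table())
  empty <- build_clusters(tibble::tibble(
    species = "none", gene = "x", chromosome = "c1", start = 1L, end = 2L,
    strand = "+", note = ""))
  empty <- empty[0, ]
  corr <- match_orthologs_across_species(pig, empty)
  n_genes <- sum(pig$n_members)
  expect_equal(sum(corr$events$kind == "unplaced"), n_genes)
})

test_that("duplicated numbers within a species are flagged as duplications", {
  hum <- build_clusters(cluster_positions("human"), anchor_table())
  pig <- build_clusters(cluster_positions("pig"), anchor_table())
  corr <- match_orthologs_across_species(hum, pig)
  dup <- dplyr::filter(corr$events, kind == "duplication")
  expect_gte(nrow(dup), 1L)
  expect_true(any(grepl("DEFB103A", dup$genes) & grepl("DEFB103B", dup$genes)))
})

test_that("the human chr8 cluster splits into the two pig clusters", {
  hum <- build_clusters(cluster_positions("human"), anchor_table())
  pig <- build_clusters(cluster_positions("pig"), anchor_table())
  ev <- compare_cluster_architecture(hum, pig)
  split <- dplyr::filter(ev, kind == "split", direction == "A_to_B")
  expect_equal(nrow(split), 1L)
  expect_equal(split$source, "human_HSA8_1")
  expect_match(split$targets, "SSC14")
  expect_match(split$targets, "SSC15")
})

test_that("identical clusters compare as conserved; mirrored comparison keeps gene sets", {
  pig <- build_clusters(cluster_positions("pig"), anchor_table())
  ev_self <- compare_cluster_architecture(pig, pig)
  fwd <- dplyr::filter(ev_self, direction == "A_to_B")
  expect_true(all(fwd$kind == "conserved"))
  hum <- build_clusters(cluster_positions("human"), anchor_table())
  ab <- compare_cluster_architecture(hum, pig)
  ba <- compare_cluster_architecture(pig, hum)
  split_ab <- dplyr::filter(ab, kind == "split", direction == "A_to_B")
  split_ba <- dplyr::filter(ba, kind == "split", direction == "B_to_A")
  norm <- function(x) sort(normalize_gene_names(strsplit(x, ",")[[1]]))
  expect_equal(norm(split_ab$genes), norm(split_ba$genes))
})

test_that("order changes are detected against a permutation oracle; reversal is conserved", {
  mk <- function(genes, chrom = "c1", sp = "sp") {
    tibble::tibble(species = sp, gene = genes, chromosome = chrom,
                   start = seq_along(genes) * 1000L,
                   end = seq_along(genes) * 1000L + 500L,
                   strand = "+", note = "")
  }
  base <- paste0("pBD", c(110, 112, 113, 114))
  a <- build_clusters(mk(base))
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 1, 3, 4), c(1, 3, 2, 4),
                c(4, 1, 2, 3))
  for (p in perms) {
    b <- build_clusters(mk(base[p], sp = "sp2"))
    ev <- compare_cluster_architecture(a, b)
    ev <- dplyr::filter(ev, direction == "A_to_B")
    expected <- if (identical(p, c(1, 2, 3, 4)) ||
                      identical(p, c(4, 3, 2, 1))) "conserved" else
      "order_change"
    expect_equal(ev$kind, expected, info = paste(p, collapse = ","))
  }
})

test_that("anchor pairs with inverted positions are rejected", {
  anc <- tibble::tibble(species = "sp", chromosome = "c1",
                        anchor_up = "X", anchor_up_alt = "",
                        anchor_down = "Y", pos_up = 100, pos_down = 10)
  pos <- tibble::tibble(species = "sp", gene = "g", chromosome = "c1",
                        start = 50L, end = 60L, strand = "+", note = "")
  expect_error(build_clusters(pos, anc), "anchor")
})

test_that("the text map lists each cluster with its anchors and numbers", {
  cl <- build_clusters(cluster_positions("pig"), anchor_table())
  lines <- render_synteny_map(cl)
  expect_length(lines, 4L)
  expect_true(any(grepl("AGPAT5..SPATA4", lines, fixed = TRUE)))
  ssc7 <- lines[grepl("SSC7", lines)]
  expect_match(ssc7, "133 - 114 - 113 - 110 - 112")  # pBD4 -> 110
})
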