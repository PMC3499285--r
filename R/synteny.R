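# Synteny-cluster construction and cross-species architecture comparison.
# Gene names are number-normalized (species prefixes stripped, legacy
# exceptions mapped through the naming table) so orthology lines are drawn
# between equal numbers, as in comparative defensin maps.

#' Normalize gene names to ortholog numbers
#'
#' Strips species prefixes (DEFB / BBD / pBD), drops duplication suffixes
#' (e.g. 103A -> 103) and pseudogene marks, and maps pig legacy names
#' through the legacy table (pBD1/-2/-3/-4 -> the numbers of their human
#' orthologs 4/1/103/110).
#'
#' @param genes Character vector of gene symbols.
#' @param legacy Legacy table, default [legacy_table()].
#' @return Character vector of ortholog-number keys.
#' @export
normalize_gene_names <- function(genes, legacy = legacy_table()) {
  keys <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    leg <- match(g, legacy$gene)
    if (!is.na(leg)) {
      keys[i] <- symbol_number(legacy$nearest_human[leg])
    } else {
      k <- symbol_number(g)
      k <- sub("[A-Za-zψ]+$", "", k)   # 103A -> 103, 117psi -> 117
      keys[i] <- k
    }
  }
  keys
}

#' Build anchor-bounded synteny clusters
#'
#' Groups genes per species and chromosome into runs separated by more
#' than `max_gap` bp, labels each run by its flanking anchor markers when
#' an anchor pair brackets it (either recorded upstream anchor candidate
#' is accepted), and otherwise by its first and last member genes. Genes
#' with chromosome `"unplaced"` are excluded from clusters and reported
#' in the `unplaced` attribute, never silently placed.
#'
#' @param positions Gene position tibble (see [cluster_positions()]):
#'   `species`, `gene`, `chromosome`, `start`, `end`, `strand`.
#' @param anchors Optional anchor tibble (see [anchor_table()]).
#' @param max_gap Maximum intra-cluster gap in bp (default 2 Mb).
#' @return A tibble of class `defensin_clusters`: `species`, `chromosome`,
#'   `cluster`, `label`, `anchor_up`, `anchor_down`, `n_members`,
#'   `members` (list of ordered position tibbles). Unclustered genes are
#'   in `attr(, "unplaced")`.
#' @export
build_clusters <- function(positions, anchors = NULL, max_gap = 2e6) {
  stopifnot(nrow(positions) > 0L)
  if (!is.null(anchors)) {
    bad <- anchors$pos_up > anchors$pos_down
    if (any(bad)) abort("anchor pair with upstream position beyond downstream")
  }
  unplaced <- filter(positions, .data$chromosome == "unplaced" |
                       is.na(.data$start))
  placed <- filter(positions, .data$chromosome != "unplaced" &
                     !is.na(.data$start))
  placed <- arrange(placed, .data$species, .data$chromosome, .data$start)
  placed <- group_by(placed, .data$species, .data$chromosome)
  placed <- mutate(placed,
                   gap = .data$start - lag(.data$end,
                                           default = dplyr::first(.data$start)),
                   cluster_idx = cumsum(.data$gap > max_gap))
  placed <- ungroup(placed)
  key <- paste(placed$species, placed$chromosome, placed$cluster_idx,
               sep = "\r")
  groups <- split(seq_len(nrow(placed)), factor(key, levels = unique(key)))
  rows <- lapply(seq_along(groups), function(i) {
    mem <- select(placed[groups[[i]], ], -"gap", -"cluster_idx")
    sp <- mem$species[1]; chrom <- mem$chromosome[1]
    cluster_idx <- placed$cluster_idx[groups[[i]][1]]
    a_up <- NA_character_; a_down <- NA_character_
    if (!is.null(anchors)) {
      arow <- filter(anchors, .data$species == sp,
                     .data$chromosome == chrom,
                     .data$pos_up <= min(mem$start),
                     .data$pos_down >= max(mem$end))
      if (nrow(arow) > 0L) {
        a_up <- arow$anchor_up[1]
        if (!is.na(arow$anchor_up_alt[1]) &&
            nzchar(arow$anchor_up_alt[1])) {
          a_up <- paste(a_up, arow$anchor_up_alt[1], sep = "|")
        }
        a_down <- arow$anchor_down[1]
      }
    }
    label <- if (!is.na(a_up)) paste(a_up, a_down, sep = "..") else
      paste(mem$gene[1], mem$gene[nrow(mem)], sep = "..")
    tibble(species = sp, chromosome = chrom,
           cluster = sprintf("%s_%s_%d", sp, chrom, cluster_idx + 1L),
           label = label, anchor_up = a_up, anchor_down = a_down,
           n_members = nrow(mem), members = list(mem))
  })
  out <- list_rbind(rows)
  # membership is a partition of the placed genes
  stopifnot(sum(out$n_members) == nrow(placed))
  attr(out, "unplaced") <- unplaced
  class(out) <- c("defensin_clusters", class(out))
  out
}

#' Match orthologous genes across two species' clusters
#'
#' Genes with equal number keys are matched; genes present in only one
#' species are flagged unplaced; a number occurring more than once within
#' one species is flagged as a duplication, with all copies recorded.
#'
#' @param clusters_a,clusters_b Outputs of [build_clusters()].
#' @param legacy Legacy table for name normalization.
#' @return A list with `map` (tibble: key, gene/cluster in each species)
#'   and `events` (duplication / unplaced flags).
#' @export
match_orthologs_across_species <- function(clusters_a, clusters_b,
                                           legacy = legacy_table()) {
  flat <- function(cl) {
    if (is.null(cl) || nrow(cl) == 0L) {
      return(tibble(gene = character(), cluster = character(),
                    pos = integer(), key = character()))
    }
    rows <- lapply(seq_len(nrow(cl)), function(i) {
      mem <- cl$members[[i]]
      tibble(gene = mem$gene, cluster = cl$cluster[i],
             pos = seq_len(nrow(mem)))
    })
    x <- list_rbind(rows)
    x$key <- normalize_gene_names(x$gene, legacy)
    x
  }
  fa <- flat(clusters_a)
  fb <- flat(clusters_b)
  events <- list()
  for (side in list(list(f = fa, tag = "A"), list(f = fb, tag = "B"))) {
    dup <- side$f$key[duplicated(side$f$key)]
    for (k in unique(dup)) {
      events[[length(events) + 1L]] <- tibble(
        kind = "duplication", species_side = side$tag, key = k,
        genes = paste(side$f$gene[side$f$key == k], collapse = ","))
    }
  }
  map <- dplyr::full_join(fa, fb, by = "key", suffix = c("_a", "_b"),
                          relationship = "many-to-many")
  lonely <- filter(map, is.na(.data$gene_a) | is.na(.data$gene_b))
  for (i in seq_len(nrow(lonely))) {
    events[[length(events) + 1L]] <- tibble(
      kind = "unplaced",
      species_side = if (is.na(lonely$gene_b[i])) "A" else "B",
      key = lonely$key[i],
      genes = paste(stats::na.omit(c(lonely$gene_a[i], lonely$gene_b[i])),
                    collapse = ","))
  }
  ev <- if (length(events)) list_rbind(events) else
    tibble(kind = character(), species_side = character(),
           key = character(), genes = character())
  list(map = map, events = ev)
}

#' Compare cluster architecture between two species
#'
#' For each cluster in species A, examines the clusters its orthologs fall
#' into in species B: `conserved` when a single target carries the same
#' shared genes in identical order (whole-cluster reversal, a strand flip,
#' still counts as conserved), `order_change` when membership matches but
#' order differs, `split` when the orthologs are distributed over two or
#' more target clusters. Duplication and unplaced flags from the
#' correspondence are appended. Comparing in the opposite direction yields
#' the mirror events (a split seen from the other side, annotated by
#' `direction`).
#'
#' @param clusters_a,clusters_b Outputs of [build_clusters()].
#' @param correspondence Output of [match_orthologs_across_species()];
#'   built if missing.
#' @param legacy Legacy table for name normalization.
#' @return A tibble of architecture events.
#' @export
compare_cluster_architecture <- function(clusters_a, clusters_b,
                                         correspondence = NULL,
                                         legacy = legacy_table()) {
  if (is.null(correspondence)) {
    correspondence <- match_orthologs_across_species(clusters_a, clusters_b,
                                                     legacy)
  }
  map <- filter(correspondence$map, !is.na(.data$gene_a),
                !is.na(.data$gene_b))
  events <- list()
  for (cl in unique(map$cluster_a)) {
    sub <- filter(map, .data$cluster_a == cl)
    targets <- unique(sub$cluster_b)
    if (length(targets) >= 2L) {
      events[[length(events) + 1L]] <- tibble(
        kind = "split", direction = "A_to_B", source = cl,
        targets = paste(sort(targets), collapse = ","),
        genes = paste(sub$gene_a, collapse = ","))
      next
    }
    # one target: compare order of the shared keys
    a_order <- sub$key[order(sub$pos_a)]
    b_order <- sub$key[order(sub$pos_b)]
    same <- identical(a_order, b_order) ||
      identical(a_order, rev(b_order))
    events[[length(events) + 1L]] <- tibble(
      kind = if (same) "conserved" else "order_change",
      direction = "A_to_B", source = cl, targets = targets,
      genes = paste(sub$gene_a, collapse = ","))
  }
  # many-to-one seen from A is a split seen from B
  for (cl in unique(map$cluster_b)) {
    sub <- filter(map, .data$cluster_b == cl)
    sources <- unique(sub$cluster_a)
    if (length(sources) >= 2L) {
      events[[length(events) + 1L]] <- tibble(
        kind = "split", direction = "B_to_A", source = cl,
        targets = paste(sort(sources), collapse = ","),
        genes = paste(sub$gene_b, collapse = ","))
    }
  }
  extra <- correspondence$events
  if (nrow(extra) > 0L) {
    extra <- tibble(kind = extra$kind,
                    direction = paste0(extra$species_side, "_side"),
                    source = NA_character_, targets = NA_character_,
                    genes = extra$genes)
    events[[length(events) + 1L]] <- extra
  }
  if (length(events) == 0L) {
    return(tibble(kind = character(), direction = character(),
                  source = character(), targets = character(),
                  genes = character()))
  }
  list_rbind(events)
}

#' Plain-text comparative synteny map
#'
#' Renders clusters per species as ordered gene-number runs with their
#' anchors, mirroring a comparative map figure in text form.
#'
#' @param clusters A `defensin_clusters` tibble (or a list of them).
#' @param legacy Legacy table for number normalization.
#' @return Character vector of lines (invisibly printed with `cat()` when
#'   interactive); returned visibly.
#' @export
render_synteny_map <- function(clusters, legacy = legacy_table()) {
  if (!inherits(clusters, "defensin_clusters") && is.list(clusters)) {
    return(unlist(lapply(clusters, render_synteny_map, legacy = legacy)))
  }
  lines <- vapply(seq_len(nrow(clusters)), function(i) {
    mem <- clusters$members[[i]]
    nums <- normalize_gene_names(mem$gene, legacy)
    sprintf("%-6s %-6s [%s]  %s", clusters$species[i],
            clusters$chromosome[i], clusters$label[i],
            paste(nums, collapse = " - "))
  }, character(1))
  lines
}
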