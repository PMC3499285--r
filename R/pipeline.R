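# End-to-end orchestration: configuration, stage sequencing (simulate ->
# discover -> annotate -> synteny -> SNPs), standard-format output, and a
# run report. One seed fans out deterministically to per-stage seeds.

#' Pipeline configuration
#'
#' Houses the stage parameters (homology thresholds, alignment penalties,
#' bootstrap settings, cluster gap, naming tolerance) and the simulation
#' settings, with the published defaults: identity > 70, coverage > 50,
#' gap open/extend 7/0.2, 1000 bootstrap replicates, 50% collapse.
#'
#' @param seed Master seed; per-stage seeds are derived as seed + stage
#'   index.
#' @param outdir Output directory.
#' @param simulate A [simulation_config()] (its seed is overridden by
#'   `seed`).
#' @param min_identity,min_coverage,rescue_identity Homology thresholds (%).
#' @param gap_open,gap_extend Protein alignment gap penalties.
#' @param n_boot,collapse Bootstrap replicates and collapse threshold (%).
#' @param tie_tol Naming tie tolerance (identity points).
#' @param max_gap Synteny cluster gap (bp).
#' @param intron_bounds Intron length bounds (bp).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L, outdir = tempfile("defmine_run_"),
                            simulate = simulation_config(),
                            min_identity = 70, min_coverage = 50,
                            rescue_identity = 80, gap_open = 7,
                            gap_extend = 0.2, n_boot = 1000L,
                            collapse = 50, tie_tol = 0.5, max_gap = 2e6,
                            intron_bounds = c(60L, 10000L)) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100,
            rescue_identity >= 0, rescue_identity <= 100,
            collapse >= 0, collapse <= 100, n_boot >= 1L, max_gap > 0)
  simulate$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 simulate = simulate, min_identity = min_identity,
                 min_coverage = min_coverage,
                 rescue_identity = rescue_identity, gap_open = gap_open,
                 gap_extend = gap_extend, n_boot = as.integer(n_boot),
                 collapse = collapse, tie_tol = tie_tol, max_gap = max_gap,
                 intron_bounds = as.integer(intron_bounds)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' YAML serialization; configurations round-trip losslessly.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$simulate <- unclass(x$simulate)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, x$simulate)
  x$simulate <- NULL
  do.call(pipeline_config, c(x, list(simulate = sim)))
}

#' Write gene models as GFF3
#'
#' @param models Gene model tibble (see [discover_genes()]); needs a
#'   `gene_id` column or row names are generated.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_gff3 <- function(models, path) {
  if (nrow(models) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  ids <- if ("gene_id" %in% names(models)) models$gene_id else
    sprintf("model%02d", seq_len(nrow(models)))
  feats <- list()
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    if (nrow(ex) == 0L) next
    feats[[length(feats) + 1L]] <- tibble(
      seqnames = models$contig[i], start = min(ex$start),
      end = max(ex$end), strand = models$strand[i], type = "gene",
      ID = ids[i], Parent = NA_character_, class = models$class[i])
    feats[[length(feats) + 1L]] <- tibble(
      seqnames = models$contig[i], start = ex$start, end = ex$end,
      strand = models$strand[i], type = "exon",
      ID = sprintf("%s.exon%d", ids[i], seq_len(nrow(ex))),
      Parent = ids[i], class = models$class[i])
  }
  ft <- list_rbind(feats)
  gr <- GenomicRanges::GRanges(
    seqnames = ft$seqnames,
    ranges = IRanges::IRanges(ft$start, ft$end), strand = ft$strand)
  gr$type <- ft$type
  gr$ID <- ft$ID
  gr$Parent <- ifelse(is.na(ft$Parent), "", ft$Parent)
  gr$class <- ft$class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Parse packaged (or user-supplied) fixture tables
#'
#' @param paths Optional named list/vector of file paths overriding the
#'   packaged fixtures; names among catalog, snps, primers, positions,
#'   anchors.
#' @return A list of typed tibbles with a `row_counts` summary.
#' @export
parse_tables <- function(paths = NULL) {
  readers <- list(
    catalog = list(f = defensin_catalog,
                   cols = c("gene", "number", "status", "pseudo")),
    snps = list(f = snp_table,
                cols = c("gene", "position", "major", "minor", "maf")),
    primers = list(f = primer_table,
                   cols = c("gene", "fwd", "rev", "product_bp")),
    positions = list(f = cluster_positions,
                     cols = c("species", "gene", "chromosome", "start")),
    anchors = list(f = anchor_table,
                   cols = c("species", "chromosome", "anchor_up",
                            "anchor_down")))
  out <- list()
  for (nm in names(readers)) {
    if (!is.null(paths) && nm %in% names(paths)) {
      x <- utils::read.delim(paths[[nm]], stringsAsFactors = FALSE,
                             check.names = FALSE)
      if (nrow(x) == 0L) abort(sprintf("fixture '%s' is empty", nm))
      missing <- setdiff(readers[[nm]]$cols, names(x))
      if (length(missing)) {
        abort(sprintf("fixture '%s' lacks column(s): %s", nm,
                      paste(missing, collapse = ", ")))
      }
      out[[nm]] <- as_tibble(x)
    } else {
      out[[nm]] <- readers[[nm]]$f()
    }
  }
  out$row_counts <- tibble(table = names(readers),
                           rows = unname(vapply(out[names(readers)],
                                                nrow, 1L)))
  out
}

#' Run the full pipeline
#'
#' Sequences the stages on a synthetic genome: simulation, discovery
#' (guided by the planted cDNAs, emulating cDNA/EST-guided boundary
#' determination), gene-model classification, a JTT/NJ tree and identity
#' matrix over the planted prepropeptides, synteny comparison of the
#' packaged pig and human coordinate fixtures, and SNP calling on the
#' packaged population fixture. All outputs are written under
#' `config$outdir` and are deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return A `defmine_run` report (stage counts, parameters, warnings).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  warnings <- character(0)
  stage <- list()

  # simulate
  sim <- simulate_genome(config$simulate)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$contigs),
                              out("genome.fasta"), width = 60L)
  truth_models <- mutate(sim$truth$genes, gene_id = .data$gene_id)
  write_models_gff3(truth_models, out("truth.gff3"))
  stage$simulate <- nrow(sim$truth$genes)

  # reference panel
  panel_tbl <- if (nrow(sim$truth$genes) > 0L) {
    make_reference_panel(sim$truth,
                         config$simulate$panel_divergence_range,
                         seed = config$seed + 1L)
  } else tibble(id = character(), sequence = character())
  if (nrow(panel_tbl) > 0L) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(panel_tbl$sequence, panel_tbl$id)),
      out("panel.fasta"), width = 60L)
  }
  stage$panel <- nrow(panel_tbl)

  # discovery
  disc <- if (nrow(panel_tbl) > 0L) {
    discover_genes(sim$contigs,
                   panel = select(panel_tbl, "id", "sequence"),
                   guides = setNames(sim$truth$genes$cdna,
                                     sim$truth$genes$gene_id),
                   min_identity = config$min_identity,
                   min_coverage = config$min_coverage,
                   rescue_identity = config$rescue_identity,
                   intron_bounds = config$intron_bounds)
  } else {
    list(candidates = find_candidate_orfs(sim$contigs),
         hits = tibble(status = character()),
         models = tibble(contig = character(), class = character(),
                         exons = list()))
  }
  utils::write.table(select(disc$candidates, -"motif_starts"),
                     out("candidates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_models_gff3(disc$models, out("models.gff3"))
  if (nrow(disc$models) > 0L) {
    utils::write.table(
      select(disc$models, "contig", "strand", "class", "n_exons",
             "span_start", "span_end"),
      out("classifications.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  n_rescued <- sum(disc$hits$status == "rescued")
  if (n_rescued > 0L) {
    warnings <- c(warnings, sprintf("%d rescue-status hits", n_rescued))
  }
  stage$candidates <- nrow(disc$candidates)
  stage$models <- nrow(disc$models)

  # phylogeny over the planted prepropeptides
  if (nrow(sim$truth$genes) >= 3L) {
    peps <- setNames(sim$truth$genes$peptide, sim$truth$genes$gene_id)
    idm <- outer(seq_along(peps), seq_along(peps),
                 Vectorize(function(i, j) {
                   if (i == j) 100 else percent_identity(peps[[i]], peps[[j]])
                 }))
    dimnames(idm) <- list(names(peps), names(peps))
    utils::write.table(round(idm, 2), out("identity_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    tree <- nj_tree(jtt_distance_matrix(peps))
    ape::write.tree(tree, out("tree.nwk"))
    stage$tree_taxa <- length(peps)
  } else {
    stage$tree_taxa <- 0L
  }

  # synteny on the packaged coordinate fixtures
  anchors <- anchor_table()
  pig_cl <- build_clusters(cluster_positions("pig"), anchors,
                           max_gap = config$max_gap)
  hum_cl <- build_clusters(cluster_positions("human"), anchors,
                           max_gap = config$max_gap)
  events <- compare_cluster_architecture(hum_cl, pig_cl)
  utils::write.table(events, out("synteny_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(render_synteny_map(pig_cl), render_synteny_map(hum_cl)),
             out("synteny_map.txt"))
  stage$clusters <- nrow(pig_cl)
  stage$synteny_events <- nrow(events)

  # variants on the packaged population fixture
  fix <- snp_population_fixture(n_animals = config$simulate$n_animals,
                                seed = config$seed + 2L)
  recs <- list()
  for (g in names(fix$populations)) {
    r <- call_snps(fix$populations[[g]]$sequences, fix$references[[g]],
                   gene = g)
    recs[[g]] <- annotate_consequence(r, fix$references)
  }
  records <- list_rbind(recs)
  # fold in MAF from the larger genotyping panel
  geno_rows <- list()
  for (i in seq_len(nrow(fix$snps))) {
    row <- fix$snps[i, ]
    pop <- simulate_population(
      fix$references[[row$gene]],
      tibble(position = row$position, major = row$major,
             minor = row$minor, minor_freq = row$maf),
      n_animals = config$simulate$n_genotyped,
      seed = config$seed + 100L + i, ensure_polymorphic = TRUE)
    g <- filter(pop$genotypes, .data$position == row$position)
    est <- estimate_maf(g$n_minor)
    geno_rows[[i]] <- tibble(gene = row$gene, position = row$position,
                             maf = est$maf,
                             n_chromosomes_genotyped = est$n_chromosomes)
  }
  records <- left_join(records, list_rbind(geno_rows),
                       by = c("gene", "position"))
  write_snp_vcf(records, out("snps.vcf"))
  assay_rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    a <- design_rflp_assay(fix$references[[r$gene]], r$position,
                           r$major, r$minor)
    if (nrow(a) > 0L) {
      assay_rows[[length(assay_rows) + 1L]] <-
        mutate(a, gene = r$gene, position = r$position, .before = 1L)
    }
  }
  assays <- if (length(assay_rows)) list_rbind(assay_rows) else
    tibble(gene = character(), position = integer(), enzyme = character())
  utils::write.table(assays, out("assays.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stage$snps <- nrow(records)
  stage$assays <- length(unique(assays$gene))

  stage_names <- names(stage)
  stage_counts <- as.integer(unlist(stage, use.names = FALSE))
  report <- structure(list(
    stages = tibble(stage = stage_names, count = stage_counts),
    params = config, outdir = config$outdir,
    warnings = warnings,
    wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "defmine_run")
  report
}

#' @export
print.defmine_run <- function(x, ...) {
  cat("defmine pipeline run (seed ", x$params$seed, ")\n", sep = "")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-16s %d\n", x$stages$stage[i], x$stages$count[i]))
  }
  if (length(x$warnings)) {
    cat("warnings:\n"); for (w in x$warnings) cat("  -", w, "\n")
  }
  cat(sprintf("outputs in %s (%.1fs)\n", x$outdir, x$wall_time))
  invisible(x)
}

#' Tidy per-stage record counts of a pipeline run
#'
#' @param x A `defmine_run`.
#' @param ... Unused.
#' @return A tibble with `stage`, `count`.
#' @method tidy defmine_run
#' @export
tidy.defmine_run <- function(x, ...) {
  x$stages
}

#' One-row summary of a pipeline run
#'
#' @param x A `defmine_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance defmine_run
#' @export
glance.defmine_run <- function(x, ...) {
  s <- setNames(as.list(x$stages$count), x$stages$stage)
  as_tibble(c(list(seed = x$params$seed), s,
              list(n_warnings = length(x$warnings),
                   wall_time = x$wall_time)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
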