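# Machine-readable encodings of the published pig beta-defensin tables,
# packaged as plain delimited text under inst/extdata and exposed as typed
# tibbles. Bp coordinates in the cluster fixture are synthetic (the source
# figures give gene order, not positions); everything else transcribes the
# printed tables.

#' Catalog of the 29 pig beta-defensin loci
#'
#' 17 newly annotated genes, 10 previously reported genes, and 2 partial
#' (psi) genes lacking exon 1.
#'
#' @return A tibble with columns `gene`, `number`, `status`
#'   (new / reported / partial_psi), `pseudo`.
#' @export
defensin_catalog <- function() {
  x <- read_fixture("gene_catalog.tsv",
                    c("gene", "number", "status", "pseudo"))
  mutate(x, pseudo = as.logical(.data$pseudo))
}

#' Published exon-2 coding SNPs
#'
#' The 8 cSNPs (7 genes): 1-based position within the exon-2 coding frame,
#' major/minor alleles, amino-acid change where nonsynonymous, the
#' differential restriction enzyme where one exists, and the estimated
#' minor allele frequency. `context_start_codon` / `context_seq` carry the
#' synthetic codon contexts used to build reference sequences consistent
#' with every printed row.
#'
#' @return A tibble with one row per SNP.
#' @export
snp_table <- function() {
  read_fixture("snp_table.tsv",
               c("gene", "position", "major", "minor", "aa_major",
                 "aa_minor", "rflp", "maf", "context_start_codon",
                 "context_seq"))
}

#' RT-PCR primer panel
#'
#' The 17 primer pairs used to distinguish genomic and cDNA amplicons by
#' product size, with annealing temperatures and expected product sizes.
#'
#' @return A tibble with one row per gene.
#' @export
primer_table <- function() {
  read_fixture("primer_table.tsv",
               c("gene", "accession", "fwd", "rev", "annealing_c",
                 "product_bp"))
}

#' Gene coordinates for synteny analysis
#'
#' Per-species chromosome assignments preserving the published gene order;
#' bp positions are synthetic placeholders at fixed spacing. Genes the
#' source leaves unplaced (pBD3, and pBD108/pBD125 which appear in the
#' catalog but in no printed cluster list) carry chromosome `"unplaced"`
#' with a note.
#'
#' @param species Optional filter, e.g. `"pig"` or `"human"`.
#' @return A tibble of gene positions.
#' @export
cluster_positions <- function(species = NULL) {
  x <- read_fixture("cluster_positions.tsv",
                    c("species", "gene", "chromosome", "start", "end",
                      "strand", "note"))
  if (!is.null(species)) x <- filter(x, .data$species %in% !!species)
  x
}

#' Cluster anchor markers
#'
#' Evolutionarily conserved flanking markers per cluster. The SSC17
#' upstream anchor is recorded with both printed candidates (ZCCHC3 and
#' TRIB3); the SSC14 cluster is bounded by its own defensin genes.
#'
#' @return A tibble with one row per anchored cluster.
#' @export
anchor_table <- function() {
  read_fixture("anchor_table.tsv",
               c("species", "chromosome", "anchor_up", "anchor_up_alt",
                 "anchor_down", "pos_up", "pos_down"))
}

#' Restriction enzyme recognition sites
#'
#' The three assay enzymes (BstNI, EcoRV, PciI) plus common 4-6 bp cutters,
#' with IUPAC-coded recognition sites.
#'
#' @return A tibble with columns `enzyme`, `site`.
#' @export
enzyme_table <- function() {
  read_fixture("enzyme_table.tsv", c("enzyme", "site"))
}

#' Legacy naming exceptions
#'
#' pBD1-4 keep their established names even though their nearest human
#' references are DEFB4, -1, -103 and -110 respectively.
#'
#' @return A tibble with columns `gene`, `nearest_human`, `keep_name`.
#' @export
legacy_table <- function() {
  x <- read_fixture("legacy_names.tsv",
                    c("gene", "nearest_human", "keep_name"))
  mutate(x, keep_name = as.logical(.data$keep_name))
}

#' Reference panel symbol list
#'
#' The 57 human, cattle and pig beta-defensin symbols used as the homology
#' reference panel, recorded verbatim (the printed human list names DEFB132
#' twice, so unique symbols sum to 56).
#'
#' @return A tibble with columns `species`, `symbol`.
#' @export
reference_symbols <- function() {
  read_fixture("reference_symbols.tsv", c("species", "symbol"))
}
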