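# ggplot2 visualisations for the main result types.

#' Plot a comparative synteny map
#'
#' Gene-order maps per species and chromosome, one horizontal track per
#' cluster, genes labeled by their ortholog numbers so conserved runs line
#' up visually across species.
#'
#' @param object A `defensin_clusters` tibble (from [build_clusters()]).
#' @param ... Additional `defensin_clusters` objects (e.g. the second
#'   species).
#' @return A ggplot object.
#' @method autoplot defensin_clusters
#' @export
autoplot.defensin_clusters <- function(object, ...) {
  clusters <- list(object, ...)
  rows <- list()
  for (cl in clusters) {
    for (i in seq_len(nrow(cl))) {
      mem <- cl$members[[i]]
      rows[[length(rows) + 1L]] <- tibble(
        species = cl$species[i],
        track = paste(cl$species[i], cl$chromosome[i], cl$label[i]),
        order = seq_len(nrow(mem)),
        number = normalize_gene_names(mem$gene))
    }
  }
  df <- list_rbind(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$track)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$track),
                       color = "grey70") +
    ggplot2::geom_label(ggplot2::aes(label = .data$number,
                                     fill = .data$species),
                        size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "gene order in cluster", y = NULL,
                  title = "Beta-defensin synteny clusters") +
    ggplot2::theme_minimal()
}

#' Plot called SNPs along the exon-2 coding frame
#'
#' Lollipop plot of minor allele frequency by coding position, colored by
#' consequence.
#'
#' @param object A `snp_calls` tibble (from [call_snps()], ideally after
#'   [annotate_consequence()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snp_calls
#' @export
autoplot.snp_calls <- function(object, ...) {
  df <- as_tibble(object)
  df$maf_plot <- if ("maf" %in% names(df) && !all(is.na(df$maf))) {
    df$maf
  } else df$maf_obs
  df$consequence[is.na(df$consequence)] <- "unannotated"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$maf_plot,
                                   color = .data$consequence)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_x") +
    ggplot2::labs(x = "exon-2 coding position (bp)",
                  y = "minor allele frequency",
                  title = "Exon-2 coding SNPs") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
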