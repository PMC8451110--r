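# Display helpers for the main result types.

#' Ideogram-style chromosome map plot
#'
#' @param map Chromosome map tibble from [chromosome_map()].
#' @param genes The gene-model tibble the map was built from (for gene
#'   positions).
#' @return A ggplot object.
#' @export
plot_chromosome_map <- function(map, genes) {
  spans <- gene_spans(genes)
  spans$chromosome[is.na(spans$chromosome) |
                     spans$chromosome %in% c("0", "chrUn")] <- "chrUn"
  ggplot2::ggplot(spans,
                  ggplot2::aes(x = .data$chromosome, y = .data$start / 1e6)) +
    ggplot2::geom_point(shape = 95, size = 6, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene_id), hjust = -0.15,
                       size = 2.5) +
    ggplot2::labs(x = NULL, y = "position (Mb)",
                  title = "Family gene localization") +
    ggplot2::theme_minimal()
}

#' Promoter architecture plot
#'
#' @param hits Hit tibble from [scan_promoters()].
#' @return A ggplot object (one row per gene, elements as coloured marks).
#' @export
plot_promoter_architecture <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$start, y = .data$gene_id,
                                     colour = .data$element)) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::labs(x = "position in upstream window (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Relative-expression bar plot with significance stars
#'
#' @param rq Tibble from [relative_quantity()].
#' @return A ggplot object.
#' @export
plot_relative_expression <- function(rq) {
  ggplot2::ggplot(rq, ggplot2::aes(x = .data$condition, y = .data$rq)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rq - .data$se,
                                        ymax = .data$rq + .data$se),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars,
                                    y = .data$rq + 2 * .data$se),
                       na.rm = TRUE, vjust = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative expression (2^-ddCt)") +
    ggplot2::theme_minimal()
}
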