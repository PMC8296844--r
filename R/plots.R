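#' Plot the gene-by-taxon pseudogene status matrix
#'
#' Tile heatmap of status categories (absent, pseudogene severity shades,
#' intact), genes on the x axis in the given order.
#'
#' @param calls Calls tibble from [scan_gene_set()].
#' @return A `ggplot` object.
#' @export
plot_status_matrix <- function(calls) {
  long <- build_status_matrix(calls, wide = FALSE)
  long$category <- factor(long$category,
                          levels = c("absent", "pseudo_severe",
                                     "pseudo_moderate", "pseudo_mild",
                                     "intact"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$taxon,
                                     fill = .data$category)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_manual(values = c(
      absent = "#08306b", pseudo_severe = "#2171b5",
      pseudo_moderate = "#6baed6", pseudo_mild = "#bdd7e7",
      intact = "#eff3ff"), drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot windowed alignment tracks
#'
#' Faceted line tracks of gap fraction, GC content and parsimony
#' substitution counts along the alignment.
#'
#' @param windows Tibble from [window_stats()].
#' @return A `ggplot` object.
#' @export
plot_window_tracks <- function(windows) {
  long <- tidyr::pivot_longer(windows,
                              c("gap_fraction", "gc",
                                "substitution_count"),
                              names_to = "track", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8", linewidth = 0.4) +
    ggplot2::geom_point(size = 0.5, color = "#2c7fb8") +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "alignment position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-gene relative evolutionary rates
#'
#' @param x A `gene_rate_fit` from [fit_gene_rates()] or its tidied
#'   tibble.
#' @return A `ggplot` object.
#' @export
plot_gene_rates <- function(x) {
  rates <- if (inherits(x, "gene_rate_fit")) tidy(x) else x
  rates <- rates[!is.na(rates$relative_rate), ]
  rates$gene <- stats::reorder(rates$gene, rates$relative_rate)
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$gene,
                                      y = .data$relative_rate)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative rate (mean 1)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gene_rate_fit <- function(object, ...) plot_gene_rates(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
NULL
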