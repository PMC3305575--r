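# ggplot2 displays for the main result types.

#' Plot the association screen
#'
#' -log10 Fisher p by genomic position, faceted by contig, with the
#' nominal significance level as a dashed line and selected variants
#' highlighted.
#'
#' @param object An `assoc_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assoc_screen <- function(object, ...) {
  d <- object$results |> filter(.data$tested)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected),
                        show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$contig),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p)),
                  title = "Single-variant case-control screen")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a site-frequency spectrum
#'
#' Stacked variant counts per frequency bin coloured by consequence class.
#'
#' @param spectrum Output of [frequency_spectrum()].
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$bin, y = .data$n,
                               fill = .data$consequence)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "minor allele frequency bin", y = "variants",
                  fill = "consequence",
                  title = "Allele frequency distribution by annotation") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot per-sample coverage summaries
#'
#' @param coverage Output of [coverage_summary()].
#' @return A ggplot.
#' @export
plot_coverage <- function(coverage) {
  d <- coverage |>
    tidyr::pivot_longer(c("pct_1x", "pct_10x", "pct_20x"),
                        names_to = "threshold", values_to = "fraction") |>
    mutate(threshold = factor(.data$threshold,
                              levels = c("pct_1x", "pct_10x", "pct_20x"),
                              labels = c(">=1X", ">=10X", ">=20X")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                  fill = .data$threshold)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of target covered",
                  fill = "depth") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
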