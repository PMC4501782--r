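#' Plot the windowed-U scan along the genome
#'
#' Windowed U against position, one panel per scaffold, with screened SNPs
#' highlighted and the U fence drawn.
#'
#' @param screen A [screen_loci()] result.
#' @param scaffolds Optional subset of scaffolds to show.
#' @return A ggplot object.
#' @export
plot_scan_profile <- function(screen, scaffolds = NULL) {
  x <- as_tibble(screen)
  if (!is.null(scaffolds)) x <- filter(x, .data$scaffold %in% scaffolds)
  thr <- attr(screen, "thresholds")
  fence <- thr$fence[thr$index == "u_bar"]
  ggplot2::ggplot(x, ggplot2::aes(.data$position / 1000, .data$u_bar)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = fence, linetype = 2,
                        colour = "firebrick") +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(data = filter(x, .data$screened),
                        colour = "firebrick", size = 0.8) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::labs(x = "position (kbp)", y = "windowed U") +
    ggplot2::theme_minimal()
}

#' Genome-wide distributions of the three windowed indices
#'
#' Histograms of windowed U, windowed G'ST and windowed delta-D' with their
#' Tukey upper fences.
#'
#' @param screen A [screen_loci()] result.
#' @param bins Histogram bins (default 60).
#' @return A ggplot object.
#' @export
plot_index_distributions <- function(screen, bins = 60) {
  thr <- attr(screen, "thresholds")
  x <- tidyr::pivot_longer(
    as_tibble(screen)[c("u_bar", "gst_bar", "delta_d_bar")],
    dplyr::everything(), names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(x, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60") +
    ggplot2::geom_vline(data = rename(thr, value = "fence"),
                        ggplot2::aes(xintercept = .data$value),
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = NULL, y = "SNPs") +
    ggplot2::theme_minimal()
}

#' @method autoplot scan_screen
#' @export
autoplot.scan_screen <- function(object, ...) {
  plot_index_distributions(object, ...)
}

#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  plot_scan_profile(object$screen, ...)
}

#' Plot the sliding cline profile of a region
#'
#' @param profile A [sliding_profile()] result.
#' @return A ggplot object.
#' @export
plot_sliding_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(.data$center / 1000, .data$mean_abs_diff,
                               colour = .data$deme)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (kbp)",
                  y = "|allele-frequency difference| vs lowest deme",
                  colour = "deme") +
    ggplot2::theme_minimal()
}

#' Fold-enrichment plot of a GO enrichment table
#'
#' @param object A [go_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot go_enrichment
#' @export
autoplot.go_enrichment <- function(object, ...) {
  x <- filter(as_tibble(object), !is.na(.data$fold_enrichment))
  ggplot2::ggplot(x, ggplot2::aes(.data$fold_enrichment,
                                  stats::reorder(.data$go_name,
                                                 .data$fold_enrichment),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "fold enrichment", y = NULL,
                  fill = "q < 0.05") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
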