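#' Plot traced unadapted fractions by generation
#'
#' Mean with min-max range per generation; when the summary carries an
#' `expected_pct` column the Mendelian halving expectation is overlaid.
#'
#' @param summary a tibble from [unadapted_generation_summary()].
#' @return A ggplot object.
#' @export
plot_generation_unadapted <- function(summary) {
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean_pct,
                                          ymin = .data$min_pct,
                                          ymax = .data$max_pct)) +
    ggplot2::labs(x = "generation", y = "unadapted genome (% of diploid)")
  if ("expected_pct" %in% names(summary)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(y = .data$expected_pct), shape = 4, colour = "red",
      size = 3)
  }
  p + ggplot2::theme_minimal()
}

#' Plot a breeding funnel metric by generation and location
#'
#' @param records a cross-record tibble (see [read_cross_records()]).
#' @param metric column name (character) of the count to plot.
#' @return A ggplot object.
#' @export
plot_breeding_funnel <- function(records, metric = "pollinated_flowers") {
  stopifnot(metric %in% names(records))
  records$generation <- factor(records$generation,
                               levels = unique(records$generation))
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$generation,
                               y = .data[[metric]],
                               fill = .data$location)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "generation", y = gsub("_", " ", metric)) +
    ggplot2::theme_minimal()
}

#' Plot traced unadapted segments along chromosomes
#'
#' @param segments a segment tibble (e.g. from [tidy()] on an
#'   `unadapted_report`, or several bound together).
#' @param map the [genetic_map()] (drawn as chromosome backbones).
#' @return A ggplot object.
#' @export
plot_traced_segments <- function(segments, map) {
  backbone <- chrom_lengths(map)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = backbone,
      ggplot2::aes(x = .data$start_cM, xend = .data$end_cM,
                   y = .data$chrom, yend = .data$chrom),
      colour = "grey80", linewidth = 2) +
    ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start_cM, xend = .data$end_cM,
                   y = .data$chrom, yend = .data$chrom,
                   colour = .data$rgene_linked),
      linewidth = 3) +
    ggplot2::labs(x = "position (cM)", y = NULL, colour = "R-gene linked") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.anova_cld <- function(object, ...) {
  letters <- object$letters
  ggplot2::ggplot(letters, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}
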