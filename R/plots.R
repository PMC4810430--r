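#' Plot a regulation summary
#'
#' Bar chart of regulation-status counts per biotype, colored by regulation
#' class (positive, negative, none).
#'
#' @param summary Tibble from [summarize_regulation()].
#' @return A ggplot object.
#' @export
plot_regulation_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$status, y = .data$n,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$biotype)) +
    ggplot2::scale_fill_manual(values = c(positive = "#c23b22",
                                          negative = "#2e6f95",
                                          none = "grey70")) +
    ggplot2::labs(x = NULL, y = "transcripts", fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the lncRNA length distribution
#'
#' @param histogram Tibble from [length_histogram()].
#' @return A ggplot object.
#' @export
plot_length_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = factor(.data$bin, levels = .data$bin),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "#2e6f95") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "length bin (nt)", y = "regulated lncRNAs") +
    ggplot2::theme_minimal()
}

#' Plot the per-chromosome distribution of regulated transcripts
#'
#' Up-class counts plotted upward and down-class counts downward, per
#' chromosome, faceted by biotype.
#'
#' @param chromosomes Tibble from [per_chromosome_counts()].
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(chromosomes) {
  long <- chromosomes |>
    tidyr::pivot_longer(c("n_up_class", "n_down_class"),
                        names_to = "direction", values_to = "n") |>
    dplyr::mutate(n = ifelse(.data$direction == "n_down_class",
                             -.data$n, .data$n))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chromosome, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$biotype), ncol = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(n_up_class = "#c23b22",
                                          n_down_class = "#2e6f95"),
                               labels = c(n_up_class = "up-class",
                                          n_down_class = "down-class")) +
    ggplot2::labs(x = NULL, y = "regulated transcripts", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a pipeline report
#'
#' The regulation-summary bar chart of the report (see
#' [plot_regulation_summary()]).
#'
#' @param object An `mts_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mts_report <- function(object, ...) {
  plot_regulation_summary(object$summary)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
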