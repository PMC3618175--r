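#' Plot a spectrogram
#'
#' @param object A `song_spectrogram`.
#' @param max_db Dynamic range below the peak to display, dB.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.song_spectrogram <- function(object, max_db = 60, ...) {
  df <- expand.grid(time = object$time, freq = object$freq / 1000)
  db <- amp_to_db(as.vector(t(object$mag)) / max(object$mag))
  df$db <- pmax(db, -max_db)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (kHz)") +
    ggplot2::theme_minimal()
}

#' Stacked repertoire-composition bars
#'
#' The per-bird view of repertoire composition: one stacked bar per bird,
#' filled by song category, ordered by the proportion of identified
#' (Common Nightingale origin) songs.
#'
#' @param summaries Row-bound [summarize_bird()] output for several birds.
#' @return A ggplot.
#' @export
plot_repertoires <- function(summaries) {
  lev <- song_category_levels()
  long <- summaries |>
    select("bird_id", all_of(lev), "proportion_identified") |>
    tidyr::pivot_longer(all_of(lev), names_to = "category",
                        values_to = "count") |>
    mutate(category = factor(.data$category, levels = rev(lev)))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$bird_id,
                                                  .data$proportion_identified),
                               y = .data$count, fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = NULL, y = "Proportion of songs", fill = "Category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Hybrid-class posterior heatmap
#'
#' @param posteriors Output of [classify_hybrids()].
#' @return A ggplot.
#' @export
plot_posteriors <- function(posteriors) {
  long <- posteriors |>
    select("individual_id", all_of(hybrid_classes())) |>
    tidyr::pivot_longer(all_of(hybrid_classes()), names_to = "class",
                        values_to = "posterior") |>
    mutate(class = factor(.data$class, levels = hybrid_classes()))
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$individual_id,
                                     fill = .data$posterior)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Posterior") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
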