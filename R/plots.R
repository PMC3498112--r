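#' Length distribution of clean reads
#'
#' Bar chart of the clean-read length histogram per library, the standard
#' first look at a small-RNA library (a Dicer-product peak at 22 nt is the
#' expected signature).
#'
#' @param cleaned Output of [clean_reads()] with a `library` column.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(cleaned) {
  df <- cleaned %>%
    filter(.data$status == "clean") %>%
    count(.data$library, length = nchar(.data$insert), name = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$n,
                                   fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "clean read length (nt)", y = "reads",
                  fill = "library") +
    ggplot2::theme_minimal()
}

#' Expression comparison plot for a differential table
#'
#' Scatter of per-miRNA normalized expression in the two libraries on log10
#' axes, coloured by the late/peak expression ratio (above 2, between 1/2
#' and 2, below 1/2).
#'
#' @param object A `mirna_de` table from [differential_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot mirna_de
autoplot.mirna_de <- function(object, ...) {
  df <- tidy(object) %>%
    filter(!.data$removed) %>%
    mutate(ratio_class = dplyr::case_when(
      .data$ne_late / .data$ne_peak > 2 ~ "ratio > 2",
      .data$ne_late / .data$ne_peak < 0.5 ~ "ratio < 1/2",
      TRUE ~ "1/2 < ratio < 2"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ne_peak, y = .data$ne_late,
                                   colour = .data$ratio_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c("ratio > 2" = "red",
                                            "1/2 < ratio < 2" = "blue",
                                            "ratio < 1/2" = "green4")) +
    ggplot2::labs(x = "normalized expression, peak lactation",
                  y = "normalized expression, late lactation",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Top enriched terms
#'
#' Bar chart of the most enriched terms by corrected P-value.
#'
#' @param object A `term_enrichment` table from [enrich_terms()].
#' @param n_terms Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot term_enrichment
autoplot.term_enrichment <- function(object, n_terms = 15, ...) {
  df <- tidy(object) %>%
    slice_head(n = n_terms) %>%
    mutate(term_id = factor(.data$term_id, levels = rev(.data$term_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$p_corrected, 1e-300)),
                                   y = .data$term_id,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 corrected P", y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
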