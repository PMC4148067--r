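#' Plot a clone location histogram
#'
#' Bar chart of the fraction of clones starting at each percent point of
#' their chromosomes, with the cumulative tail distribution overlaid.
#'
#' @param object A `location_histogram` from [location_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot location_histogram
#' @export
autoplot.location_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fraction), fill = "grey35") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative * max(.data$fraction)),
                       colour = "firebrick") +
    ggplot2::labs(x = "percent point of chromosome",
                  y = "fraction of clones starting here",
                  title = "Clone start positions along chromosomes") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment test result
#'
#' Histogram of the matched random-library null statistics with the
#' observed value marked.
#'
#' @param object An `enrichment_result` from [enrichment_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "statistic on matched random libraries",
                  y = "replicates",
                  subtitle = sprintf("observed = %.3g, empirical p = %.3g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Compare repeat category percentages across libraries
#'
#' Dodged bar chart of the mean percent of clone sequence per repeat
#' category for each library summary supplied.
#'
#' @param ... Named `repeat_library_summary` objects (names used as
#'   library labels when the summaries carry none).
#' @return A ggplot object.
#' @export
plot_repeat_categories <- function(...) {
  summaries <- list(...)
  nms <- names(summaries)
  df <- bind_rows(purrr::imap(summaries, function(s, nm) {
    lab <- if (!is.na(s$library)) s$library else nm
    tidy(s) %>%
      filter(.data$field == "pct") %>%
      mutate(library = lab)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$mean,
                                   fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean % of clone sequence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
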