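#' Plot a network similarity matrix
#'
#' Heatmap of the mouse-by-mouse similarity matrix; the diagonal (within-
#' mouse similarity) should stand out when individual variation is present.
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy(object)
  mice <- rownames(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$mouse_col, levels = mice),
    y = factor(.data$mouse_row, levels = rev(mice)),
    fill = .data$similarity
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "z(r)") +
    ggplot2::labs(x = "first half", y = "second half",
                  title = "Network similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot observed vs predicted behaviour of a CPM
#'
#' @param object A `cpm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpm_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "magenta", linewidth = 0.5) +
    ggplot2::labs(
      x = "observed mean latency to fall (s)",
      y = "predicted (LOOCV)",
      title = sprintf("CPM prediction, r = %.2f", object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Per-mouse group vs individual similarity plot
#'
#' Paired plot of group and individual similarity per mouse, the standard
#' visual for the individuality effect.
#'
#' @param summary Tibble from [summarize_similarity()].
#' @return A ggplot object.
#' @export
plot_similarity_summary <- function(summary) {
  df <- tidyr::pivot_longer(summary, c("group", "individual"),
                            names_to = "level", values_to = "similarity")
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$similarity)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$mouse), colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", colour = "magenta",
                          width = 0.3, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "network similarity z(r)") +
    ggplot2::theme_minimal()
}

#' Module-pair fraction heatmap for thresholded edge statistics
#'
#' @param top A [top_percentile_edges()] result.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_module_fractions <- function(top, title = "top-percentile edges") {
  ggplot2::ggplot(top$fractions, ggplot2::aes(
    .data$module_a, .data$module_b, fill = .data$fraction
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "fraction") +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Identification null distribution plot
#'
#' Histogram of shuffled identification rates with the observed rates marked.
#'
#' @param ident An [identification_null()] result.
#' @return A ggplot object.
#' @export
plot_identification_null <- function(ident) {
  df <- tibble::tibble(rate = c(ident$null_column, ident$null_row),
                       direction = rep(c("column", "row"),
                                       c(length(ident$null_column),
                                         length(ident$null_row))))
  obs <- tibble::tibble(rate = c(ident$rate_column, ident$rate_row),
                        direction = c("column", "row"))
  ggplot2::ggplot(df, ggplot2::aes(.data$rate)) +
    ggplot2::geom_histogram(binwidth = NULL, bins = 30, fill = "grey75") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$rate),
                        colour = "magenta") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "identification rate", y = "shuffles") +
    ggplot2::theme_minimal()
}

#' Rotarod learning-curve plot
#'
#' Per-trial latencies per mouse with the group mean highlighted.
#'
#' @param behavior Tibble from [sample_behavior()].
#' @return A ggplot object.
#' @export
plot_behavior <- function(behavior) {
  df <- behavior |>
    tidyr::pivot_longer(dplyr::starts_with("day"), names_to = "trial",
                        values_to = "latency_s") |>
    dplyr::mutate(trial = factor(.data$trial, levels = unique(.data$trial)))
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$latency_s)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$mouse), colour = "grey80") +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean, geom = "line",
                          colour = "magenta", linewidth = 1) +
    ggplot2::labs(x = NULL, y = "latency to fall (s)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
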