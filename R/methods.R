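#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a similarity matrix into a long tibble
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return Tibble: `mouse_row` (second half), `mouse_col` (first half),
#'   `similarity`, `within` (logical diagonal flag).
#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(m, .name_repair = "minimal") |>
    stats::setNames(colnames(m)) |>
    dplyr::mutate(mouse_row = rownames(m), .before = 1) |>
    tidyr::pivot_longer(-"mouse_row", names_to = "mouse_col",
                        values_to = "similarity") |>
    dplyr::mutate(within = .data$mouse_row == .data$mouse_col)
}

#' Glance at a similarity matrix
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return One-row tibble: `n_mice`, mean individual and group similarity,
#'   mean normalized effect, and the two identification rates.
#' @export
glance.similarity_matrix <- function(x, ...) {
  sm <- summarize_similarity(x)
  idr <- identification(x)
  tibble::tibble(
    n_mice = nrow(x),
    mean_individual = mean(sm$individual),
    mean_group = mean(sm$group),
    mean_normalized_effect = mean(sm$normalized_effect),
    rate_column = idr$rate_column,
    rate_row = idr$rate_row
  )
}

#' Tidy a CPM result
#'
#' @param x A `cpm_result`.
#' @param ... Unused.
#' @return The per-mouse predictions tibble with a `residual` column.
#' @export
tidy.cpm_result <- function(x, ...) {
  dplyr::mutate(x$predictions, residual = .data$observed - .data$predicted)
}

#' Glance at a CPM result
#'
#' @param x A `cpm_result`.
#' @param ... Unused.
#' @return One-row tibble: `n_mice`, `r`, consensus set sizes, fold count,
#'   number of fallback folds.
#' @export
glance.cpm_result <- function(x, ...) {
  tibble::tibble(
    n_mice = nrow(x$predictions),
    r = x$r,
    n_consensus_positive = length(x$consensus$positive),
    n_consensus_negative = length(x$consensus$negative),
    n_folds = length(x$folds),
    n_fallback_folds = length(x$warnings)
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Network similarity matrix (", nrow(x), " mice; rows = second half, ",
      "columns = first half)\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' @export
print.cpm_result <- function(x, ...) {
  g <- glance(x)
  cat("Connectome-based predictive model (LOOCV, ", g$n_folds, " folds)\n",
      "  observed vs predicted r = ", round(g$r, 3), "\n",
      "  consensus edges: ", g$n_consensus_positive, " positive, ",
      g$n_consensus_negative, " negative\n", sep = "")
  if (g$n_fallback_folds > 0) {
    cat("  ", g$n_fallback_folds, " fold(s) fell back to the training mean\n")
  }
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec: ", x$n_mice, " mice x ", x$n_sessions,
      " sessions x ", x$n_runs_per_session, " runs x ", x$n_frames_per_run,
      " frames (TR ", x$tr_seconds, " s), ", nrow(x$parcellation),
      " nodes\n  sigma: group ", x$sigma_group, ", individual ",
      x$sigma_individual, ", session ", x$sigma_session, "; seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
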