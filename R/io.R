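#' Read and write the package's plain-text formats
#'
#' All tables are written at full precision so numeric round trips are exact
#' to the stored digits: parcellation and motion as TSV, connectomes as
#' square CSV with node-name header row/column and a zero diagonal, edge
#' vectors as TSV keyed `nodeA|nodeB`, behaviour as TSV, provenance as JSON.
#'
#' @param parcellation,connectome,edges,motion,behavior Objects to write.
#' @param path File path.
#' @param node_names Node labels for the connectome / edge-vector writers.
#' @name fc_io
NULL

#' @rdname fc_io
#' @export
write_parcellation <- function(parcellation, path) {
  readr::write_tsv(parcellation, path)
  invisible(path)
}

#' @rdname fc_io
#' @export
read_parcellation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    node = readr::col_character(), hemisphere = readr::col_character(),
    module = readr::col_character(), system = readr::col_character()
  ))
}

#' @rdname fc_io
#' @export
write_connectome <- function(connectome, path) {
  stopifnot(is.matrix(connectome))
  m <- connectome
  diag(m) <- 0
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- colnames(m) %||% paste0("n", seq_len(ncol(m)))
  df <- dplyr::bind_cols(tibble::tibble(node = names(df)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname fc_io
#' @export
read_connectome <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    node = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$node
  if (!identical(rownames(m), colnames(m))) {
    stop("connectome file header and node column disagree")
  }
  m
}

#' @rdname fc_io
#' @export
write_edge_vector <- function(edges, node_names, path) {
  ij <- upper_pairs(length(node_names))
  readr::write_tsv(tibble::tibble(
    pair = paste(node_names[ij[, 1]], node_names[ij[, 2]], sep = "|"),
    value = edges
  ), path)
  invisible(path)
}

#' @rdname fc_io
#' @export
write_motion <- function(motion, path) {
  readr::write_tsv(motion, path)
  invisible(path)
}

#' @rdname fc_io
#' @export
read_motion <- function(path) {
  readr::read_tsv(path, col_types = readr::cols())
}

#' @rdname fc_io
#' @export
write_behavior <- function(behavior, path) {
  readr::write_tsv(behavior, path)
  invisible(path)
}

#' @rdname fc_io
#' @export
read_behavior <- function(path) {
  readr::read_tsv(path, col_types = readr::cols())
}

#' Write every pipeline output under one directory
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  cohort <- result$cohort
  write_parcellation(cohort$parcellation, fp("parcellation.tsv"))
  write_motion(result$scrub$masks, fp("motion_masks.tsv"))
  readr::write_tsv(result$scrub$sessions, fp("session_inclusion.tsv"))
  write_behavior(cohort$behavior, fp("behavior.tsv"))

  S <- result$similarity$matrix
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(mouse = rownames(S)),
                     tibble::as_tibble(unclass(S), .name_repair = "minimal")),
    fp("similarity_matrix.csv")
  )
  readr::write_tsv(result$similarity$summary, fp("similarity_summary.tsv"))
  readr::write_tsv(result$edge_stats, fp("edge_statistics.tsv"))
  readr::write_tsv(result$cpm$observed$predictions, fp("cpm_predictions.tsv"))
  readr::write_tsv(result$log, fp("run_log.tsv"))

  ident <- result$similarity$identification
  jsonlite::write_json(list(
    rate_column = ident$rate_column, rate_row = ident$rate_row,
    p_column = ident$p_column, p_row = ident$p_row,
    convention = ident$convention
  ), fp("identification.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    r = result$cpm$observed$r, p = result$cpm$p,
    consensus_positive = result$cpm$observed$consensus$positive,
    consensus_negative = result$cpm$observed$consensus$negative
  ), fp("cpm_result.json"), auto_unbox = TRUE, digits = NA)

  save_config(result$config, fp("config.yaml"))
  jsonlite::write_json(
    list(package = "fcfingerprint", seed = result$config$seed,
         cohort_seed = result$config$cohort$seed,
         n_mice = result$config$cohort$n_mice,
         timestamp = format(Sys.time(), tz = "UTC")),
    fp("provenance.json"), auto_unbox = TRUE
  )
  invisible(out_dir)
}
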