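#' Paired Student t-test
#'
#' Thin wrapper over [stats::t.test()] on the paired differences, with the
#' degenerate-case validation the pipeline relies on.
#'
#' @param x,y Paired numeric samples of equal length.
#' @return A list: `t`, `df`, `p` (two-sided), `mean_difference`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) stop("constant paired differences: t undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Cohen's d for a paired t statistic
#'
#' `d = t / sqrt(n)`, the standardized mean difference implied by a paired t
#' statistic on n pairs.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @return Cohen's d.
#' @examples
#' paired_cohens_d(7.32, 16) # 1.83
#' @export
paired_cohens_d <- function(t, n) {
  if (n < 2) stop("need at least 2 pairs")
  t / sqrt(n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]), with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, monotone in and no smaller than the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pipeline configuration
#'
#' Collects every threshold, seed and convention flag of the full analysis in
#' one serializable list. Thresholds default to the study design values:
#' 50 um FD, 50-frame run and 192-frame session minima, alpha 0.05 edge
#' selection, 99th-percentile edge display, 1000 shuffles.
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohort (the
#'   `simulate` stage); alternatively load inputs yourself and call the stage
#'   functions directly.
#' @param fd_um,min_segment,min_run,min_session Scrubbing thresholds.
#' @param alpha,pct,shuffles Analysis thresholds.
#' @param p_convention `"add_one"` or `"rank"` permutation p convention.
#' @param subsample_convention `"unordered"` or `"ordered"` session pairing.
#' @param aggregate `"concatenate"` (kept frames of a session's runs are
#'   concatenated before correlation) or `"average"` (per-run connectomes
#'   averaged) — relevant only when building from time series.
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            fd_um = 50, min_segment = 5,
                            min_run = 50, min_session = 192,
                            alpha = 0.05, pct = 99, shuffles = 1000,
                            p_convention = "add_one",
                            subsample_convention = "unordered",
                            aggregate = "concatenate",
                            seed = 1L) {
  structure(list(
    cohort = cohort, fd_um = fd_um, min_segment = min_segment,
    min_run = min_run, min_session = min_session, alpha = alpha, pct = pct,
    shuffles = shuffles, p_convention = p_convention,
    subsample_convention = subsample_convention, aggregate = aggregate,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' YAML round trip of every scalar field (the cohort's parcellation is
#' restored from its module sizes and system map).
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   restored config.
#' @export
save_config <- function(config, path) {
  co <- config$cohort
  p <- co$parcellation
  sizes <- table(p$module[p$hemisphere == "L"])[unique(p$module)]
  sysmap <- stats::setNames(
    p$system[!duplicated(p$module)], p$module[!duplicated(p$module)]
  )
  payload <- list(
    cohort = list(
      n_mice = co$n_mice, n_sessions = co$n_sessions,
      n_runs_per_session = co$n_runs_per_session,
      n_frames_per_run = co$n_frames_per_run, tr_seconds = co$tr_seconds,
      module_sizes = as.list(stats::setNames(as.integer(sizes), names(sizes))),
      system_map = as.list(sysmap),
      sigma_group = co$sigma_group, sigma_individual = co$sigma_individual,
      sigma_session = co$sigma_session,
      module_multipliers = as.list(co$module_multipliers),
      behavior = co$behavior_spec, motion = co$motion_spec, seed = co$seed
    ),
    thresholds = config[c("fd_um", "min_segment", "min_run", "min_session",
                          "alpha", "pct", "shuffles")],
    conventions = config[c("p_convention", "subsample_convention", "aggregate")],
    seed = config$seed
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  co <- y$cohort
  sizes <- unlist(co$module_sizes)
  parcellation <- make_parcellation(sum(sizes), sizes, unlist(co$system_map))
  b <- co$behavior
  mm <- if (length(co$module_multipliers)) unlist(co$module_multipliers) else NULL
  spec <- cohort_spec(
    n_mice = co$n_mice, n_sessions = co$n_sessions,
    n_runs_per_session = co$n_runs_per_session,
    n_frames_per_run = co$n_frames_per_run, tr_seconds = co$tr_seconds,
    parcellation = parcellation, sigma_group = co$sigma_group,
    sigma_individual = co$sigma_individual, sigma_session = co$sigma_session,
    module_multipliers = mm,
    behavior_spec = behavior_spec(unlist(b$planted_edges) %||% integer(),
                                  b$beta, b$noise_sd, b$baseline, b$shared_sd),
    motion_spec = co$motion, seed = co$seed
  )
  pipeline_config(
    cohort = spec, fd_um = y$thresholds$fd_um,
    min_segment = y$thresholds$min_segment, min_run = y$thresholds$min_run,
    min_session = y$thresholds$min_session, alpha = y$thresholds$alpha,
    pct = y$thresholds$pct, shuffles = y$thresholds$shuffles,
    p_convention = y$conventions$p_convention,
    subsample_convention = y$conventions$subsample_convention,
    aggregate = y$conventions$aggregate, seed = y$seed
  )
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage: simulate the cohort, scrub its motion traces and apply
#' run/session exclusions, build frame-balanced half-connectomes, run the
#' similarity/identification/edge-statistics analyses, and fit the CPM of
#' behaviour with permutation significance. Fully reproducible under the
#' config's seeds; every fallback or exclusion taken at runtime is collected
#' in the returned `log`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there as plain-text tables plus a provenance JSON.
#' @return A list with elements `cohort`, `scrub` (masks + inclusion report),
#'   `halves` (per-mouse split), `similarity` (matrix, per-mouse summary,
#'   identification with null), `edge_stats` (tibble with `phi`, `dp`),
#'   `subsample` (per-k results), `systems` (association/sensory reruns),
#'   `cpm` (permutation result + category enrichment), `log` (tibble).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logs <- list()
  note <- function(stage, msg) {
    logs[[length(logs) + 1]] <<- tibble::tibble(stage = stage, message = msg)
  }

  cohort <- sample_cohort(config$cohort)
  note("simulate", sprintf("cohort: %d mice x %d sessions, %d nodes, seed %d",
                           config$cohort$n_mice, config$cohort$n_sessions,
                           nrow(cohort$parcellation), config$cohort$seed))

  scrub <- scrub_cohort(cohort$motion, config$fd_um, config$min_segment,
                        config$min_run, config$min_session)
  for (i in which(!scrub$sessions$included)) {
    note("scrub", sprintf("mouse %s session %s excluded: %s",
                          scrub$sessions$mouse[i], scrub$sessions$session[i],
                          scrub$sessions$reason[i]))
  }

  # frame-balanced halves per mouse from the session frame totals
  sess <- scrub$sessions |> dplyr::filter(.data$included)
  run_fd <- scrub$masks |>
    dplyr::group_by(.data$mouse, .data$session) |>
    dplyr::summarise(mean_fd = mean(.data$fd_um), .groups = "drop")
  n_mice <- config$cohort$n_mice
  halves <- vector("list", n_mice)
  eligible <- logical(n_mice)
  for (m in seq_len(n_mice)) {
    sm <- sess |>
      dplyr::filter(.data$mouse == m) |>
      dplyr::left_join(run_fd, by = c("mouse", "session")) |>
      dplyr::transmute(session = .data$session, n_frames = .data$n_frames,
                       mean_fd = .data$mean_fd)
    if (nrow(sm) < 6) {
      note("split", sprintf("mouse %d has %d valid sessions; CPM only", m, nrow(sm)))
      next
    }
    if (nrow(sm) > 7) sm <- dplyr::slice_min(sm, .data$mean_fd, n = 7)
    halves[[m]] <- split_halves(sm)
    eligible[m] <- TRUE
  }

  if (sum(eligible) < 2) {
    stop("split: fewer than 2 mice have six valid sessions; ",
         "similarity analyses are not possible for this cohort")
  }

  half_edges <- function(which_half) {
    t(vapply(which(eligible), function(m) {
      ids <- halves[[m]][[which_half]]
      colMeans(cohort$sessions[m, ids, , drop = TRUE])
    }, numeric(dim(cohort$sessions)[3])))
  }
  h1 <- half_edges("half_a")
  h2 <- half_edges("half_b")
  rownames(h1) <- rownames(h2) <- paste0("mouse", which(eligible))

  S <- similarity_matrix(h1, h2)
  summary_tbl <- summarize_similarity(S)
  ident <- identification_null(S, n_shuffles = config$shuffles,
                               seed = stream_seed(config$seed, 11),
                               convention = config$p_convention)

  zn1 <- znorm_edges(h1)
  zn2 <- znorm_edges(h2)
  edge_stats <- tibble::tibble(
    edge = seq_len(ncol(h1)),
    phi = group_consistency(zn1, zn2),
    dp = differential_power(zn1, zn2)
  )
  top <- list(
    dp = top_percentile_edges(edge_stats$dp, cohort$parcellation, config$pct),
    phi = top_percentile_edges(edge_stats$phi, cohort$parcellation, config$pct)
  )

  subsample <- lapply(stats::setNames(1:3, paste0("k", 1:3)), function(k) {
    session_subsample(cohort$sessions[eligible, , , drop = FALSE], k,
                      convention = config$subsample_convention)
  })

  # system-restricted reruns use the identical code path on subset edges
  et <- edge_table(cohort$parcellation)
  systems <- lapply(c(association = "A:A", sensory = "S:S"), function(cat) {
    idx <- et$edge[et$category == cat]
    Ssub <- similarity_matrix(h1[, idx, drop = FALSE], h2[, idx, drop = FALSE])
    list(summary = summarize_similarity(Ssub), identification = identification(Ssub))
  })

  mean_conn <- t(vapply(seq_len(n_mice), function(m) {
    colMeans(cohort$sessions[m, , , drop = TRUE])
  }, numeric(dim(cohort$sessions)[3])))
  rownames(mean_conn) <- paste0("mouse", seq_len(n_mice))
  cpm <- cpm_permutation(mean_conn, cohort$behavior$mean_latency_s,
                         alpha = config$alpha, n_shuffles = config$shuffles,
                         seed = stream_seed(config$seed, 12),
                         convention = config$p_convention)
  for (w in cpm$observed$warnings) note("cpm", w)
  enrichment <- list(
    positive = category_enrichment(cpm$observed$consensus$positive, cohort$parcellation),
    negative = category_enrichment(cpm$observed$consensus$negative, cohort$parcellation)
  )

  result <- list(
    cohort = cohort, scrub = scrub, halves = halves,
    similarity = list(matrix = S, summary = summary_tbl, identification = ident),
    edge_stats = edge_stats, top_edges = top, subsample = subsample,
    systems = systems,
    cpm = c(cpm, list(enrichment = enrichment)),
    log = dplyr::bind_rows(logs),
    config = config
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}
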