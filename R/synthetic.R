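#' Specify a synthetic cohort
#'
#' Collects every parameter of the generative model in one validated list.
#' The model is additive on the Fisher-z edge scale: each session connectome
#' of mouse *m* equals a group-shared edge pattern, plus a stable per-mouse
#' deviation, plus fresh session noise, all Gaussian and independent across
#' edges. Defaults mirror the awake-mouse study design the package emulates:
#' 16 mice, 6 sessions of 4 runs of 198 usable frames at TR 2.5 s, 86
#' cortical nodes in 6 modules.
#'
#' @param n_mice,n_sessions,n_runs_per_session,n_frames_per_run Cohort shape.
#' @param tr_seconds Repetition time in seconds.
#' @param parcellation Parcellation tibble; defaults to the 86-node fixture.
#' @param sigma_group SD of the group-shared edge pattern (z units).
#' @param sigma_individual SD of the stable per-mouse edge deviation.
#' @param sigma_session SD of per-session edge noise.
#' @param module_multipliers Optional named per-module multipliers on
#'   `sigma_individual`; an edge's multiplier is the geometric mean of its two
#'   endpoint modules' values (used e.g. to make posterior modules more
#'   individually variable in DP positive controls).
#' @param behavior_spec List from [behavior_spec()]: planted edges, coupling,
#'   noise, and the shared-latent strength.
#' @param motion_spec List: `outlier_prob` (per-frame probability of a
#'   censorable movement), `fd_outlier_scale` (um), `fd_baseline` (um),
#'   `dvars_baseline`, `dvars_sd`.
#' @param seed Master integer seed; all per-mouse/per-session streams are
#'   derived from it by a fixed offset scheme, so enlarging the cohort does
#'   not reshuffle existing animals.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_mice = 16,
                        n_sessions = 6,
                        n_runs_per_session = 4,
                        n_frames_per_run = 198,
                        tr_seconds = 2.5,
                        parcellation = make_parcellation(),
                        sigma_group = 0.30,
                        sigma_individual = 0.10,
                        sigma_session = 0.28,
                        module_multipliers = NULL,
                        behavior_spec = fcfingerprint::behavior_spec(),
                        motion_spec = list(outlier_prob = 0.03,
                                           fd_outlier_scale = 60,
                                           fd_baseline = 12,
                                           dvars_baseline = 100,
                                           dvars_sd = 5),
                        seed = 1L) {
  counts <- c(n_mice = n_mice, n_sessions = n_sessions,
              n_runs_per_session = n_runs_per_session,
              n_frames_per_run = n_frames_per_run)
  if (any(counts <= 0)) stop("all cohort counts must be positive")
  scales <- c(sigma_group, sigma_individual, sigma_session, tr_seconds)
  if (any(scales < 0)) stop("scales must be non-negative")
  E <- n_edges(nrow(parcellation))
  pe <- behavior_spec$planted_edges
  if (length(pe) && (any(pe < 1) || any(pe > E))) {
    stop("planted edges out of range: connectome has ", E, " edges")
  }
  if (!is.null(module_multipliers)) {
    miss <- setdiff(unique(parcellation$module), names(module_multipliers))
    if (length(miss)) stop("module_multipliers missing: ", paste(miss, collapse = ", "))
  }
  structure(list(
    n_mice = as.integer(n_mice), n_sessions = as.integer(n_sessions),
    n_runs_per_session = as.integer(n_runs_per_session),
    n_frames_per_run = as.integer(n_frames_per_run),
    tr_seconds = tr_seconds, parcellation = parcellation,
    sigma_group = sigma_group, sigma_individual = sigma_individual,
    sigma_session = sigma_session, module_multipliers = module_multipliers,
    behavior_spec = behavior_spec, motion_spec = motion_spec,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Specify the behavior-generating model
#'
#' Behaviour is a per-mouse scalar (mean rotarod latency to fall, seconds)
#' equal to `baseline + beta * mean(individual deviation over planted edges)
#' + N(0, noise_sd)`. When `shared_sd > 0`, a per-mouse latent factor scaled
#' by `shared_sd` is added to the individual deviation of every planted edge,
#' so the planted edges co-vary and each one carries the behavioural signal —
#' the construction used for CPM recovery checks. `shared_sd = 0` reduces to
#' the plain edge-independent model.
#'
#' @param planted_edges Integer canonical edge indices (may be empty).
#' @param beta Coupling coefficient (seconds per z unit).
#' @param noise_sd Behavioural noise SD, seconds.
#' @param baseline Baseline mean latency, seconds (an arbitrary scale choice;
#'   the study's task prints no latency values).
#' @param shared_sd SD of the shared latent added to planted edges (z units).
#' @return A `behavior_spec` list.
#' @export
behavior_spec <- function(planted_edges = integer(), beta = 0,
                          noise_sd = 10, baseline = 150, shared_sd = 0) {
  if (length(planted_edges) == 0 && beta != 0) {
    stop("beta != 0 requires a non-empty planted edge set")
  }
  list(planted_edges = as.integer(planted_edges), beta = beta,
       noise_sd = noise_sd, baseline = baseline, shared_sd = shared_sd)
}

# deterministic sub-seed derivation: fold ids into [0, 2^31 - 2]
stream_seed <- function(master, ...) {
  ids <- c(master, ...)
  s <- 0
  for (x in ids) s <- (s * 69069 + x * 2654435761) %% 2147483647
  as.integer(s)
}

edge_sigma_multiplier <- function(parcellation, module_multipliers) {
  if (is.null(module_multipliers)) return(1)
  et <- edge_table(parcellation)
  sqrt(module_multipliers[et$module_a] * module_multipliers[et$module_b])
}

#' Sample a full synthetic cohort
#'
#' Draws the group edge pattern, per-mouse stable deviations, per-session
#' connectomes, per-run motion traces and the behaviour table, all
#' deterministically from the spec's master seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` list: `parcellation`, `true_group_edges`
#'   (length-E vector), `true_individual_edges` (mice-by-E matrix),
#'   `sessions` (mice-by-sessions-by-E array of z edge vectors), `motion`
#'   (long tibble), `behavior` (tibble from [sample_behavior()]), `spec`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$parcellation
  E <- n_edges(nrow(p))
  mult <- edge_sigma_multiplier(p, spec$module_multipliers)

  set.seed(stream_seed(spec$seed, 101))
  group <- stats::rnorm(E, 0, spec$sigma_group)

  indiv <- matrix(0, spec$n_mice, E)
  latent <- numeric(spec$n_mice)
  bs <- spec$behavior_spec
  for (m in seq_len(spec$n_mice)) {
    set.seed(stream_seed(spec$seed, 202, m))
    indiv[m, ] <- stats::rnorm(E, 0, spec$sigma_individual) * mult
    latent[m] <- stats::rnorm(1)
    if (bs$shared_sd > 0 && length(bs$planted_edges)) {
      indiv[m, bs$planted_edges] <- indiv[m, bs$planted_edges] +
        bs$shared_sd * latent[m]
    }
  }

  sessions <- array(
    0, dim = c(spec$n_mice, spec$n_sessions, E),
    dimnames = list(paste0("mouse", seq_len(spec$n_mice)),
                    paste0("session", seq_len(spec$n_sessions)), NULL)
  )
  for (m in seq_len(spec$n_mice)) {
    for (s in seq_len(spec$n_sessions)) {
      set.seed(stream_seed(spec$seed, 303, m, s))
      sessions[m, s, ] <- group + indiv[m, ] +
        stats::rnorm(E, 0, spec$sigma_session)
    }
  }

  ms <- spec$motion_spec
  grid <- tidyr::expand_grid(
    mouse = seq_len(spec$n_mice),
    session = seq_len(spec$n_sessions),
    run = seq_len(spec$n_runs_per_session)
  )
  motion <- purrr::pmap_dfr(grid, function(mouse, session, run) {
    tr <- sample_motion(
      n_frames = spec$n_frames_per_run,
      outlier_prob = ms$outlier_prob,
      fd_outlier_scale = ms$fd_outlier_scale,
      seed = stream_seed(spec$seed, 404, mouse, session, run),
      fd_baseline = ms$fd_baseline,
      dvars_baseline = ms$dvars_baseline,
      dvars_sd = ms$dvars_sd
    )
    dplyr::mutate(tr, mouse = mouse, session = session, run = run,
                  .before = 1)
  })

  cohort <- structure(list(
    parcellation = p,
    true_group_edges = group,
    true_individual_edges = indiv,
    sessions = sessions,
    motion = motion,
    behavior = NULL,
    spec = spec
  ), class = "synthetic_cohort")
  cohort$behavior <- sample_behavior(
    cohort, planted_edges = bs$planted_edges, beta = bs$beta,
    noise_sd = bs$noise_sd, seed = stream_seed(spec$seed, 505),
    baseline = bs$baseline
  )
  cohort
}

#' One mouse/session edge vector or z-matrix from a cohort
#' @param cohort A `synthetic_cohort`.
#' @param mouse,session Indices.
#' @param as_matrix Return the symmetric z-matrix instead of the edge vector.
#' @return Numeric edge vector (default) or matrix.
#' @export
session_connectome <- function(cohort, mouse, session, as_matrix = FALSE) {
  v <- cohort$sessions[mouse, session, ]
  if (as_matrix) edges_to_matrix(v, cohort$parcellation$node) else v
}

#' Sample a parcel time series with a target correlation structure
#'
#' Draws multivariate Gaussian frames whose population correlation matrix is
#' the inverse-Fisher transform of the target z-matrix. If the implied
#' correlation matrix is not positive semi-definite it is repaired by clipping
#' negative eigenvalues and rescaling to unit diagonal.
#'
#' @param target_z Symmetric matrix of Fisher z values (diagonal ignored).
#' @param n_frames Number of frames to draw.
#' @param seed Integer seed.
#' @return Frames-by-nodes matrix (column names from the target's dimnames).
#' @export
sample_timeseries <- function(target_z, n_frames, seed) {
  stopifnot(is.matrix(target_z), nrow(target_z) == ncol(target_z))
  if (max(abs(target_z - t(target_z))) > 1e-8) stop("target matrix must be symmetric")
  n <- nrow(target_z)
  if (n_frames < n + 1) {
    warning("n_frames <= n_nodes: sample correlation matrix will be rank-deficient")
  }
  r <- inverse_fisher_z(target_z)
  diag(r) <- 1
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < 0) {
    vals <- pmax(e$values, 1e-8)
    r <- e$vectors %*% diag(vals) %*% t(e$vectors)
    r <- stats::cov2cor(r)
    e <- eigen(r, symmetric = TRUE)
  }
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  set.seed(seed)
  x <- matrix(stats::rnorm(n_frames * n), n_frames, n) %*% root
  colnames(x) <- colnames(target_z)
  x
}

#' Sample a per-run motion trace
#'
#' Baseline framewise displacement sits well below the 50 um censoring
#' threshold (folded normal around `fd_baseline`); with probability
#' `outlier_prob` a frame is a movement whose FD exceeds the threshold by an
#' exponential excess of scale `fd_outlier_scale`. DVARS is a matched trace:
#' Gaussian baseline with large excursions on the same outlier frames.
#'
#' @param n_frames Frames in the run.
#' @param outlier_prob Per-frame movement probability in `[0, 1]`.
#' @param fd_outlier_scale Scale (um) of FD excess above threshold on
#'   movement frames.
#' @param seed Integer seed.
#' @param fd_baseline,dvars_baseline,dvars_sd Baseline trace parameters.
#' @return Tibble with columns `frame`, `fd_um`, `dvars`, and logical
#'   `outlier` (ground truth, for tests).
#' @export
sample_motion <- function(n_frames, outlier_prob = 0.03, fd_outlier_scale = 60,
                          seed = 1L, fd_baseline = 12, dvars_baseline = 100,
                          dvars_sd = 5) {
  if (outlier_prob < 0 || outlier_prob > 1) stop("outlier_prob must lie in [0, 1]")
  set.seed(seed)
  out <- stats::runif(n_frames) < outlier_prob
  fd <- abs(stats::rnorm(n_frames, fd_baseline, fd_baseline / 3))
  fd <- pmin(fd, 45) # baseline never trips the 50 um rule on its own
  fd[out] <- 50 + stats::rexp(sum(out), 1 / fd_outlier_scale)
  dv <- stats::rnorm(n_frames, dvars_baseline, dvars_sd)
  dv[out] <- dv[out] + 10 * dvars_sd
  tibble::tibble(frame = seq_len(n_frames), fd_um = fd, dvars = abs(dv),
                 outlier = out)
}

#' Sample the behaviour table of a cohort
#'
#' Per-mouse mean rotarod latency to fall: `baseline + beta * mean(true
#' individual deviation over planted edges) + N(0, noise_sd)`, truncated at
#' zero. Also emits 2 days x 4 trials of per-trial latencies following a
#' saturating learning curve whose mean equals the per-mouse scalar exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param planted_edges Integer canonical edge indices.
#' @param beta Coupling coefficient.
#' @param noise_sd Behavioural noise SD.
#' @param seed Integer seed.
#' @param baseline Baseline latency, seconds.
#' @return Tibble: `mouse`, `mean_latency_s`, and `day<d>_trial<t>` columns.
#' @export
sample_behavior <- function(cohort, planted_edges = integer(), beta = 0,
                            noise_sd = 10, seed = 1L, baseline = 150) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$true_individual_edges)
  if (n < 2) stop("behaviour requires at least 2 mice")
  if (length(planted_edges) == 0 && beta != 0) {
    stop("beta != 0 requires a non-empty planted edge set")
  }
  signal <- if (length(planted_edges)) {
    rowMeans(cohort$true_individual_edges[, planted_edges, drop = FALSE])
  } else 0
  set.seed(seed)
  latency <- pmax(baseline + beta * signal + stats::rnorm(n, 0, noise_sd), 0)

  # saturating learning curve over 2 days x 4 trials, rescaled so the
  # per-mouse trial mean equals the scalar exactly
  curve <- 1 - exp(-seq_len(8) / 3)
  curve <- curve / mean(curve)
  trials <- outer(latency, curve)
  colnames(trials) <- paste0("day", rep(1:2, each = 4), "_trial", rep(1:4, 2))
  dplyr::bind_cols(
    tibble::tibble(mouse = seq_len(n), mean_latency_s = latency),
    tibble::as_tibble(trials)
  )
}
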