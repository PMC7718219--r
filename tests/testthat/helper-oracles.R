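# Independent brute-force oracles. These deliberately re-state each rule as
# literal loops/enumeration, separate from the package implementations.

# frame censoring: flag -> augment -> short-segment removal, frame by frame
oracle_censor_mask <- function(fd, dvars, fd_thresh = 50, min_segment = 5,
                               dvars_thresh = NULL) {
  n <- length(fd)
  if (is.null(dvars_thresh)) {
    q25 <- unname(quantile(dvars, 0.25, type = 7))
    q75 <- unname(quantile(dvars, 0.75, type = 7))
    dvars_thresh <- q75 + 1.5 * (q75 - q25)
  }
  flagged <- logical(n)
  for (t in seq_len(n)) {
    if (fd[t] > fd_thresh || dvars[t] > dvars_thresh) flagged[t] <- TRUE
  }
  keep <- !flagged
  for (t in seq_len(n)) {
    if (flagged[t] && t < n) keep[t + 1] <- FALSE
  }
  # enumerate maximal kept segments
  t <- 1
  while (t <= n) {
    if (keep[t]) {
      s <- t
      while (t <= n && keep[t]) t <- t + 1
      if ((t - s) < min_segment) keep[s:(t - 1)] <- FALSE
    } else {
      t <- t + 1
    }
  }
  keep
}

# frame-balanced 3+3 partition by full enumeration of all 20 ordered subsets
oracle_split <- function(frames) {
  stopifnot(length(frames) == 6)
  subs <- combn(6, 3, simplify = FALSE)
  subs <- Filter(function(s) 1 %in% s, subs) # unordered: half A holds session 1
  diffs <- vapply(subs, function(s) abs(sum(frames[s]) - sum(frames[-s])),
                  numeric(1))
  best <- subs[[which.min(diffs)]] # combn order is lexicographic
  list(half_a = best, half_b = setdiff(1:6, best), frame_diff = min(diffs))
}

# strict-argmax identification by explicit loops
oracle_identification <- function(S) {
  n <- nrow(S)
  col_ok <- row_ok <- logical(n)
  for (i in seq_len(n)) {
    col_ok[i] <- sum(S[, i] >= S[i, i]) == 1 # only the diagonal itself
    row_ok[i] <- sum(S[i, ] >= S[i, i]) == 1
  }
  c(rate_column = mean(col_ok), rate_row = mean(row_ok))
}

# edgewise Phi and DP by triple loops over mice and cross pairs
oracle_phi_dp <- function(h1, h2) {
  n <- nrow(h1)
  E <- ncol(h1)
  phi <- dp <- numeric(E)
  for (e in seq_len(E)) {
    w <- h1[, e] * h2[, e]
    phi[e] <- mean(w)
    wins <- 0
    total <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        wins <- wins + (w[i] > h1[i, e] * h2[j, e])
        wins <- wins + (w[i] > h1[j, e] * h2[i, e])
        total <- total + 2
      }
    }
    dp[e] <- wins / total
  }
  list(phi = phi, dp = dp)
}

# consensus by looping over folds and testing membership edge by edge
oracle_consensus <- function(sets) {
  all_edges <- sort(unique(unlist(sets)))
  keep <- logical(length(all_edges))
  for (k in seq_along(all_edges)) {
    keep[k] <- all(vapply(sets, function(s) all_edges[k] %in% s, logical(1)))
  }
  all_edges[keep]
}

# small 2-module parcellation used throughout the unit tests
tiny_parcellation <- function(n_per_hemi = 4) {
  make_parcellation(
    n_per_hemi,
    c(AA = ceiling(n_per_hemi / 2), SS = floor(n_per_hemi / 2)),
    c(AA = "association", SS = "sensory")
  )
}

# compact cohort spec for fast simulation-based tests
tiny_cohort_spec <- function(n_mice = 8, seed = 42, n_runs_per_session = 1, ...) {
  cohort_spec(
    n_mice = n_mice, n_sessions = 6, n_runs_per_session = n_runs_per_session,
    n_frames_per_run = 198, parcellation = tiny_parcellation(6),
    seed = seed, ...
  )
}

# per-mouse half-connectome edge matrices from a cohort's sessions array
cohort_halves <- function(cohort, idx_a = 1:3, idx_b = 4:6) {
  n <- dim(cohort$sessions)[1]
  h <- function(idx) {
    t(vapply(seq_len(n), function(m) colMeans(cohort$sessions[m, idx, , drop = TRUE]),
             numeric(dim(cohort$sessions)[3])))
  }
  list(h1 = h(idx_a), h2 = h(idx_b))
}

# per-mouse session-averaged edge matrix (CPM input)
cohort_mean_edges <- function(cohort) {
  n <- dim(cohort$sessions)[1]
  t(vapply(seq_len(n), function(m) colMeans(cohort$sessions[m, , , drop = TRUE]),
           numeric(dim(cohort$sessions)[3])))
}
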