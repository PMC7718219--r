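#' Fisher z-transform of a Pearson correlation
#'
#' `atanh(r)` after clipping `r` into `[-1 + 1e-7, 1 - 1e-7]`, so that
#' perfectly correlated pairs map to a large finite value instead of
#' infinity while the ordering of correlations is preserved.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Inverse Fisher transform
#' @param z Fisher z value(s).
#' @return Correlation value(s) `tanh(z)`.
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Build a Fisher-z connectome from a parcel time series
#'
#' Pairwise Pearson correlation over the (already censored) frames, Fisher
#' z-transformed, with zero diagonal by convention. Run-level series belonging
#' to one session are expected to be concatenated before calling (see
#' `aggregate` in [run_pipeline()] for the per-run-then-average variant).
#'
#' @param ts Numeric frames-by-nodes matrix; columns in parcellation node
#'   order (column names, if present, must match `parcellation$node`).
#' @param parcellation Optional parcellation tibble used to validate node
#'   order and label the output.
#' @return A symmetric n-by-n matrix of Fisher z values with attribute
#'   `n_frames_used`.
#' @export
build_connectome <- function(ts, parcellation = NULL) {
  stopifnot(is.matrix(ts))
  if (nrow(ts) < 3) stop("need at least 3 frames to correlate")
  if (!is.null(parcellation)) {
    if (ncol(ts) != nrow(parcellation)) {
      stop("time series has ", ncol(ts), " nodes but parcellation has ",
           nrow(parcellation))
    }
    if (!is.null(colnames(ts)) && !identical(colnames(ts), parcellation$node)) {
      stop("time-series node order does not match the parcellation")
    }
    colnames(ts) <- parcellation$node
  }
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance node(s): ", paste(bad, collapse = ", "))
  }
  z <- fisher_z(stats::cor(ts))
  diag(z) <- 0
  attr(z, "n_frames_used") <- nrow(ts)
  z
}

#' Average Fisher-z connectomes entrywise
#'
#' @param connectomes A list of equally sized symmetric z-matrices.
#' @return Their entrywise mean; `n_frames_used` attributes are summed when
#'   present on every input.
#' @export
average_connectomes <- function(connectomes) {
  stopifnot(is.list(connectomes), length(connectomes) > 0)
  dims <- vapply(connectomes, function(m) dim(m), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("connectomes have mixed dimensions; are they from the same parcellation?")
  }
  nms <- lapply(connectomes, rownames)
  if (!all(vapply(nms, identical, logical(1), nms[[1]]))) {
    stop("connectome node labels differ; mixed parcellations are not averageable")
  }
  avg <- Reduce(`+`, connectomes) / length(connectomes)
  frames <- vapply(connectomes, function(m) {
    f <- attr(m, "n_frames_used")
    if (is.null(f)) NA_real_ else as.numeric(f)
  }, numeric(1))
  attr(avg, "n_frames_used") <- if (anyNA(frames)) NULL else sum(frames)
  avg
}

#' Split six sessions into two frame-balanced halves
#'
#' Partitions a mouse's six usable sessions into two halves of three sessions,
#' minimising the absolute difference in total included frames between the
#' halves, by exhaustive search over the 10 unordered 3+3 partitions. Ties are
#' broken by the lexicographically smallest session set in half A (half A is
#' the half containing the first session). If seven sessions are supplied with
#' a `mean_fd` column, the session with the highest head motion is dropped
#' first; mice with fewer than six usable sessions are rejected (such animals
#' are carried in the CPM analysis only).
#'
#' @param sessions Tibble with one row per usable session: columns `session`
#'   and `n_frames`, optionally `mean_fd` (required for the 7-session drop).
#' @return A list with integer vectors `half_a`, `half_b` (session ids),
#'   `frame_diff`, and `dropped` (id of a discarded 7th session or `NULL`).
#' @export
split_halves <- function(sessions) {
  stopifnot(is.data.frame(sessions), all(c("session", "n_frames") %in% names(sessions)))
  sessions <- dplyr::arrange(sessions, .data$session)
  dropped <- NULL
  if (nrow(sessions) == 7) {
    if (!"mean_fd" %in% names(sessions)) {
      stop("7 sessions supplied: need `mean_fd` to drop the highest-motion session")
    }
    drop_i <- which.max(sessions$mean_fd)
    dropped <- sessions$session[drop_i]
    sessions <- sessions[-drop_i, ]
  }
  if (nrow(sessions) != 6) {
    stop("need exactly 6 usable sessions to split (got ", nrow(sessions),
         "); mice with fewer than six valid sessions enter the CPM analysis only")
  }
  ids <- sessions$session
  frames <- sessions$n_frames
  # the 10 unordered partitions = 3-subsets containing the first session,
  # enumerated in lexicographic order so the tie-break is the first minimum
  subsets <- utils::combn(2:6, 2)
  best <- NULL
  for (k in seq_len(ncol(subsets))) {
    a <- c(1L, subsets[, k])
    d <- abs(sum(frames[a]) - sum(frames[-a]))
    if (is.null(best) || d < best$d) best <- list(a = a, d = d)
  }
  list(
    half_a = ids[best$a],
    half_b = ids[setdiff(1:6, best$a)],
    frame_diff = best$d,
    dropped = dropped
  )
}

#' Restrict a connectome to a node subset
#'
#' Principal submatrix over the given nodes (in parcellation order), used for
#' the association-only and sensory-only system analyses. Edge indices are
#' re-derived for the reduced parcellation.
#'
#' @param connectome Symmetric z-matrix with node-name dimnames.
#' @param nodes Character vector of node ids to retain.
#' @return The submatrix, with the same attributes convention.
#' @export
subset_nodes <- function(connectome, nodes) {
  if (length(nodes) == 0) stop("empty node subset")
  if (is.null(rownames(connectome))) stop("connectome must carry node names")
  unknown <- setdiff(nodes, rownames(connectome))
  if (length(unknown)) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  keep <- rownames(connectome)[rownames(connectome) %in% nodes]
  out <- connectome[keep, keep]
  attr(out, "n_frames_used") <- attr(connectome, "n_frames_used")
  out
}

#' Group-level sparsity mask over edges
#'
#' Ranks edges by the group-mean Fisher z across the supplied per-mouse
#' average connectomes and keeps the strongest `density` fraction. The mask is
#' intended to be applied uniformly to all mice downstream (the control
#' analysis restricting the similarity pipeline to strong, anatomically
#' plausible connections).
#'
#' @param connectomes List of per-mouse average z-matrices (same parcellation).
#' @param density Fraction of edges to retain, in `(0, 1]`.
#' @return Integer vector of retained canonical edge indices.
#' @export
sparsity_mask <- function(connectomes, density) {
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  grp <- matrix_to_edges(average_connectomes(connectomes))
  k <- round(density * length(grp))
  if (k < 2) stop("density of ", density, " keeps fewer than 2 edges")
  sort(order(grp, decreasing = TRUE)[seq_len(k)])
}
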