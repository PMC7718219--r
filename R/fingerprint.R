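#' Network similarity matrix between two half-connectomes per mouse
#'
#' Entry `(i, j)` is the Fisher z-transformed Pearson correlation between
#' mouse *j*'s first-half edge vector (columns) and mouse *i*'s second-half
#' edge vector (rows), over all canonical edges. The matrix is generally
#' asymmetric; its diagonal is the within-mouse (individual) similarity.
#'
#' @param halves_1,halves_2 Mice-by-edges numeric matrices (same mouse order,
#'   same edge indexing). Row names, if present, label the mice.
#' @return A `similarity_matrix`: n-by-n matrix of z values, rows = second
#'   half, columns = first half.
#' @export
similarity_matrix <- function(halves_1, halves_2) {
  stopifnot(is.matrix(halves_1), is.matrix(halves_2),
            identical(dim(halves_1), dim(halves_2)))
  if (!is.null(rownames(halves_1)) && !is.null(rownames(halves_2)) &&
      !identical(rownames(halves_1), rownames(halves_2))) {
    stop("the two halves list different mice")
  }
  sds <- c(apply(halves_1, 1, stats::sd), apply(halves_2, 1, stats::sd))
  if (any(sds == 0)) stop("constant edge vector: similarity undefined")
  s <- fisher_z(stats::cor(t(halves_1), t(halves_2)))
  s <- t(s) # rows = second half (halves_2), columns = first half (halves_1)
  mice <- rownames(halves_1) %||% paste0("mouse", seq_len(nrow(halves_1)))
  dimnames(s) <- list(mice, mice)
  class(s) <- c("similarity_matrix", class(s))
  s
}

#' Per-mouse individual and group similarity
#'
#' Individual similarity of mouse *i* is the diagonal entry `S[i, i]`; group
#' similarity is the mean of the `2(n-1)` off-diagonal entries in its row and
#' column combined.
#'
#' @param S A [similarity_matrix()].
#' @param parcel_mode Apply the parcel-level rounding rules of
#'   [normalized_individual_effect()] when computing `normalized_effect`.
#' @return Tibble: `mouse`, `individual`, `group`, `normalized_effect`.
#' @export
summarize_similarity <- function(S, parcel_mode = FALSE) {
  n <- nrow(S)
  if (n < 2) stop("need at least 2 mice to summarise similarity")
  purrr::map_dfr(seq_len(n), function(i) {
    off <- c(S[i, -i], S[-i, i])
    ind <- S[i, i]
    grp <- mean(off)
    tibble::tibble(
      mouse = rownames(S)[i],
      individual = ind,
      group = grp,
      normalized_effect = normalized_individual_effect(ind, grp,
                                                       parcel_mode = parcel_mode)
    )
  })
}

#' Normalized relative individual effect
#'
#' `(individual - group) / individual`: the added similarity of a mouse's own
#' connectome over the group, as a fraction of its individual similarity. In
#' parcel mode (used for the per-region analysis, where low-signal parcels can
#' produce negative similarities), negative similarity inputs are first
#' rounded to 0.001 and a negative resulting effect is rounded to 0.
#'
#' @param individual,group Similarity values (Fisher z).
#' @param parcel_mode Logical, apply the parcel-level rounding rules.
#' @return The effect fraction.
#' @export
normalized_individual_effect <- function(individual, group, parcel_mode = FALSE) {
  if (parcel_mode) {
    individual <- ifelse(individual < 0, 0.001, individual)
    group <- ifelse(group < 0, 0.001, group)
    pmax((individual - group) / individual, 0)
  } else {
    if (any(individual == 0)) stop("individual similarity of 0: effect undefined")
    (individual - group) / individual
  }
}

#' Connectome-based identification rates
#'
#' A mouse is identified in the column direction when its diagonal similarity
#' is the strict maximum of its column (its first-half connectome is closest
#' to its own second half among all mice), and likewise over rows for the
#' other direction. Ties count as failures.
#'
#' @param S A [similarity_matrix()].
#' @return A list: `rate_column`, `rate_row` (fractions), and logical vectors
#'   `correct_column`, `correct_row` per mouse.
#' @export
identification <- function(S) {
  n <- nrow(S)
  if (n < 2) stop("need at least 2 mice to identify")
  d <- diag(S)
  correct_col <- vapply(seq_len(n), function(j) all(S[-j, j] < d[j]), logical(1))
  correct_row <- vapply(seq_len(n), function(i) all(S[i, -i] < d[i]), logical(1))
  list(
    rate_column = mean(correct_col),
    rate_row = mean(correct_row),
    correct_column = correct_col,
    correct_row = correct_row
  )
}

#' Permutation null for identification rates
#'
#' Each shuffle randomly reassigns mouse identities in one half of the data
#' (a permutation of the rows for the column-direction rate, of the columns
#' for the row-direction rate) and recomputes the identification rates. The
#' p-value per direction is `(1 + #\{null >= observed\}) / (n_shuffles + 1)`,
#' or `#\{null >= observed\} / n_shuffles` under the rank convention.
#'
#' @param S A [similarity_matrix()].
#' @param n_shuffles Number of identity shuffles.
#' @param seed Integer seed.
#' @param convention `"add_one"` (default) or `"rank"` p-value convention.
#' @return A list: observed `rate_column`/`rate_row`, matrices of null rates,
#'   and `p_column`, `p_row`.
#' @export
identification_null <- function(S, n_shuffles = 1000, seed = 1L,
                                convention = c("add_one", "rank")) {
  convention <- match.arg(convention)
  n <- nrow(S)
  if (n < 3) stop("need at least 3 mice for a meaningful shuffle null")
  obs <- identification(S)
  set.seed(seed)
  null_col <- numeric(n_shuffles)
  null_row <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    pr <- sample.int(n) # new identities for the second half (rows)
    null_col[b] <- identification(S[pr, , drop = FALSE])$rate_column
    pc <- sample.int(n) # new identities for the first half (columns)
    null_row[b] <- identification(S[, pc, drop = FALSE])$rate_row
  }
  pval <- function(null, observed) {
    if (convention == "add_one") (1 + sum(null >= observed)) / (n_shuffles + 1)
    else sum(null >= observed) / n_shuffles
  }
  list(
    rate_column = obs$rate_column, rate_row = obs$rate_row,
    null_column = null_col, null_row = null_row,
    p_column = pval(null_col, obs$rate_column),
    p_row = pval(null_row, obs$rate_row),
    convention = convention
  )
}

#' Parcel-level similarity summaries
#'
#' For each node, similarity is computed on its connectivity profile (its
#' `n - 1` off-diagonal entries) between the two halves, then summarised with
#' the parcel-mode rounding rules. Optionally averages the normalized effect
#' between mirrored hemispheric nodes.
#'
#' @param halves_1,halves_2 Lists of per-mouse full z-matrices (same order).
#' @param parcellation Parcellation tibble.
#' @param average_hemispheres Average `normalized_effect` between the L/R
#'   copies of each (module, within-module index) pair.
#' @return Tibble: `node` (or `module`+`idx` when averaging hemispheres),
#'   per-parcel means of `individual`, `group`, `normalized_effect`, and a
#'   `flagged` column marking parcels with a constant profile in any mouse.
#' @export
parcel_similarity <- function(halves_1, halves_2, parcellation,
                              average_hemispheres = FALSE) {
  stopifnot(length(halves_1) == length(halves_2), length(halves_1) >= 2)
  n_nodes <- nrow(parcellation)
  per_parcel <- purrr::map_dfr(seq_len(n_nodes), function(k) {
    h1 <- t(vapply(halves_1, function(m) m[k, -k], numeric(n_nodes - 1)))
    h2 <- t(vapply(halves_2, function(m) m[k, -k], numeric(n_nodes - 1)))
    if (any(apply(h1, 1, stats::sd) == 0) || any(apply(h2, 1, stats::sd) == 0)) {
      return(tibble::tibble(node = parcellation$node[k], individual = NA_real_,
                            group = NA_real_, normalized_effect = NA_real_,
                            flagged = TRUE))
    }
    sm <- summarize_similarity(similarity_matrix(h1, h2), parcel_mode = TRUE)
    tibble::tibble(node = parcellation$node[k],
                   individual = mean(sm$individual), group = mean(sm$group),
                   normalized_effect = mean(sm$normalized_effect),
                   flagged = FALSE)
  })
  if (!average_hemispheres) return(per_parcel)
  per_parcel |>
    dplyr::left_join(parcellation, by = "node") |>
    dplyr::mutate(idx = sub(".*_(\\d+)$", "\\1", .data$node)) |>
    dplyr::group_by(.data$module, .data$idx) |>
    dplyr::summarise(
      individual = mean(.data$individual), group = mean(.data$group),
      normalized_effect = mean(.data$normalized_effect),
      flagged = any(.data$flagged), .groups = "drop"
    )
}

#' Spearman correlation of parcel effects with an external score table
#'
#' Used to relate per-parcel individuality to e.g. anatomical hierarchy
#' scores supplied by the user.
#'
#' @param effects Tibble with a key column and an `effect` value column.
#' @param scores Tibble with the same key column and a `score` column.
#' @param key Name of the key column (default `"node"`).
#' @return A list: `rho` and two-sided `p` (t-approximation).
#' @export
hierarchy_correlation <- function(effects, scores, key = "node") {
  merged <- dplyr::inner_join(effects, scores, by = key)
  unmatched <- c(setdiff(effects[[key]], scores[[key]]),
                 setdiff(scores[[key]], effects[[key]]))
  if (length(unmatched)) {
    stop("unmatched parcel key(s): ", paste(unmatched, collapse = ", "))
  }
  if (nrow(merged) < 4) stop("need at least 4 matched parcels")
  sp <- spearman_t_approx(merged$effect, merged$score)
  list(rho = sp$rho, p = sp$p)
}

# Spearman rho with the two-sided t-approximation p-value
spearman_t_approx <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Z-normalize an edge vector
#'
#' Subtracts the mean and divides by the standard deviation across the
#' vector's edges — the per-connectome normalization applied before the
#' edgewise product statistics.
#'
#' @param v Numeric edge vector (or mice-by-edges matrix, normalized per row).
#' @return The normalized vector/matrix (mean 0, SD 1 per connectome).
#' @export
znorm_edges <- function(v) {
  if (is.matrix(v)) return(t(apply(v, 1, znorm_edges)))
  s <- stats::sd(v)
  if (s == 0) stop("constant edge vector cannot be z-normalized")
  (v - mean(v)) / s
}

#' Group consistency (Phi) per edge
#'
#' The mean, over mice, of the edgewise product of each mouse's two
#' z-normalized half-connectomes. High-Phi edges are strong (or weak) in the
#' same way in everyone.
#'
#' @param halves_1,halves_2 Mice-by-edges matrices of z-normalized edge
#'   vectors (see [znorm_edges()]).
#' @return Numeric vector, Phi per edge.
#' @export
group_consistency <- function(halves_1, halves_2) {
  stopifnot(identical(dim(halves_1), dim(halves_2)), nrow(halves_1) >= 1)
  colMeans(halves_1 * halves_2)
}

#' Differential power (DP) per edge
#'
#' The empirical probability that a mouse's within-animal edgewise product
#' exceeds a cross-animal product: for each edge, the fraction — over all
#' ordered mouse pairs `(i, j != i)` and both cross directions (mouse i's
#' half 1 against mouse j's half 2, and mouse j's half 1 against mouse i's
#' half 2) — of strict inequalities
#' `h1[i]*h2[i] > h1[i]*h2[j]` and `h1[i]*h2[i] > h1[j]*h2[i]`.
#' High-DP edges are the ones that make individuals identifiable.
#'
#' @inheritParams group_consistency
#' @return Numeric vector, DP per edge, each in `[0, 1]`.
#' @export
differential_power <- function(halves_1, halves_2) {
  stopifnot(identical(dim(halves_1), dim(halves_2)))
  n <- nrow(halves_1)
  if (n < 2) stop("DP requires at least 2 mice")
  E <- ncol(halves_1)
  within <- halves_1 * halves_2 # n x E
  wins <- numeric(E)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # direction 1: mouse i's half 1 against the others' half 2
    cross1 <- halves_2[others, , drop = FALSE] *
      matrix(halves_1[i, ], length(others), E, byrow = TRUE)
    # direction 2: the others' half 1 against mouse i's half 2
    cross2 <- halves_1[others, , drop = FALSE] *
      matrix(halves_2[i, ], length(others), E, byrow = TRUE)
    w <- matrix(within[i, ], length(others), E, byrow = TRUE)
    wins <- wins + colSums(w > cross1) + colSums(w > cross2)
  }
  wins / (2 * n * (n - 1))
}

#' Edges above a percentile, with module-pair fractions
#'
#' Selects edges whose value strictly exceeds the `pct`-th percentile (linear
#' interpolation percentile; ties at the threshold are excluded), and
#' tabulates, for every module pair, the share of that pair's edges present in
#' the selection — the data behind the thresholded DP/Phi module plots.
#'
#' @param values Numeric vector over canonical edges.
#' @param parcellation Parcellation tibble.
#' @param pct Percentile threshold (default 99, the "top 1%").
#' @return A list: `edges` (integer indices), `threshold`, and `fractions`
#'   (tibble `module_a`, `module_b`, `n_edges`, `n_selected`, `fraction`).
#' @export
top_percentile_edges <- function(values, parcellation, pct = 99) {
  thr <- stats::quantile(values, pct / 100, names = FALSE, type = 7)
  sel <- which(values > thr)
  et <- edge_table(parcellation)
  mods <- unique(parcellation$module)
  fractions <- et |>
    dplyr::mutate(
      m1 = pmin(match(.data$module_a, mods), match(.data$module_b, mods)),
      m2 = pmax(match(.data$module_a, mods), match(.data$module_b, mods)),
      selected = .data$edge %in% sel
    ) |>
    dplyr::group_by(module_a = mods[.data$m1], module_b = mods[.data$m2]) |>
    dplyr::summarise(n_edges = dplyr::n(), n_selected = sum(.data$selected),
                     fraction = mean(.data$selected), .groups = "drop")
  list(edges = sel, threshold = thr, fractions = fractions)
}

#' Similarity and identification as a function of sessions per connectome
#'
#' For `k` sessions per half, enumerates the combinations of two disjoint
#' k-subsets of each mouse's six sessions (unordered by default: 15, 45 and
#' 10 combinations for k = 1, 2, 3; the ordered convention doubles the k = 3
#' count to 20), builds the averaged half-connectomes for each combination,
#' and runs the similarity and identification analyses. Similarity values are
#' averaged over combinations per mouse; identification rates are kept per
#' combination.
#'
#' @param sessions Mice-by-sessions-by-edges array (6 sessions per mouse), as
#'   in a `synthetic_cohort`'s `sessions` element.
#' @param k Sessions per connectome: 1, 2 or 3.
#' @param convention `"unordered"` (default) or `"ordered"` pairing of the two
#'   k-subsets.
#' @return A list: `similarity` (per-mouse tibble of combination-averaged
#'   `individual`, `group`, `normalized_effect`), `rates` (per-combination
#'   tibble of `rate_column`, `rate_row`), `n_combinations`.
#' @export
session_subsample <- function(sessions, k, convention = c("unordered", "ordered")) {
  convention <- match.arg(convention)
  stopifnot(length(dim(sessions)) == 3)
  n_sess <- dim(sessions)[2]
  if (n_sess != 6) stop("session subsampling expects 6 sessions per mouse")
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")

  subsets <- utils::combn(n_sess, k, simplify = FALSE)
  pairs <- list()
  for (a in seq_along(subsets)) {
    for (b in seq_along(subsets)) {
      if (length(intersect(subsets[[a]], subsets[[b]]))) next
      if (convention == "unordered" && b <= a) next
      if (convention == "ordered" && b == a) next
      pairs[[length(pairs) + 1]] <- list(A = subsets[[a]], B = subsets[[b]])
    }
  }
  if (convention == "ordered" && k < 3) {
    # ordered double-counts every unordered pair; collapse for k < 3 where the
    # two conventions coincide in the study's printed counts
    pairs <- pairs[vapply(pairs, function(p) p$A[1] < p$B[1], logical(1))]
  }

  half_mean <- function(idx) {
    m <- sessions[, idx, , drop = FALSE]
    apply(m, c(1, 3), mean)
  }
  mice <- dimnames(sessions)[[1]] %||% paste0("mouse", seq_len(dim(sessions)[1]))

  sims <- vector("list", length(pairs))
  rates <- vector("list", length(pairs))
  for (ci in seq_along(pairs)) {
    h1 <- half_mean(pairs[[ci]]$A)
    h2 <- half_mean(pairs[[ci]]$B)
    rownames(h1) <- rownames(h2) <- mice
    S <- similarity_matrix(h1, h2)
    sims[[ci]] <- summarize_similarity(S)
    idr <- identification(S)
    rates[[ci]] <- tibble::tibble(combination = ci,
                                  rate_column = idr$rate_column,
                                  rate_row = idr$rate_row)
  }
  similarity <- dplyr::bind_rows(sims) |>
    dplyr::group_by(.data$mouse) |>
    dplyr::summarise(individual = mean(.data$individual),
                     group = mean(.data$group),
                     normalized_effect = mean(.data$normalized_effect),
                     .groups = "drop")
  list(similarity = similarity, rates = dplyr::bind_rows(rates),
       n_combinations = length(pairs))
}
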