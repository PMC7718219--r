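#' Build a mirrored cortical parcellation table
#'
#' Defines the ordered node table that fixes the canonical edge ordering used
#' throughout the package. Nodes are mirrored across hemispheres: the left
#' hemisphere block comes first, then the right, and within each hemisphere
#' nodes are ordered by module (in the order `module_sizes` is given) and by
#' within-module index.
#'
#' @param n_per_hemisphere Number of cortical nodes per hemisphere.
#' @param module_sizes Named integer vector, nodes per module per hemisphere.
#'   Must sum to `n_per_hemisphere`.
#' @param system_map Named character vector mapping every module to either
#'   `"association"` or `"sensory"`.
#'
#' @return A tibble with one row per node and columns `node` (unique id),
#'   `hemisphere` (`"L"`/`"R"`), `module`, and `system`, in canonical order.
#'
#' @examples
#' p <- make_parcellation(3, c(A = 2, B = 1), c(A = "association", B = "sensory"))
#' nrow(p) # 6 nodes
#' @export
make_parcellation <- function(n_per_hemisphere = 43,
                              module_sizes = default_module_sizes(),
                              system_map = default_system_map()) {
  stopifnot(is.numeric(n_per_hemisphere), n_per_hemisphere >= 1)
  if (is.null(names(module_sizes)) || any(!nzchar(names(module_sizes)))) {
    stop("`module_sizes` must be a named vector of per-module node counts")
  }
  if (sum(module_sizes) != n_per_hemisphere) {
    stop(sprintf(
      "module sizes sum to %d but n_per_hemisphere is %d",
      sum(module_sizes), n_per_hemisphere
    ))
  }
  missing_sys <- setdiff(names(module_sizes), names(system_map))
  if (length(missing_sys)) {
    stop("no system assignment for module(s): ", paste(missing_sys, collapse = ", "))
  }
  bad_sys <- setdiff(unname(system_map[names(module_sizes)]), c("association", "sensory"))
  if (length(bad_sys)) {
    stop("system must be 'association' or 'sensory', got: ", paste(bad_sys, collapse = ", "))
  }

  one_hemi <- function(h) {
    tibble::tibble(
      hemisphere = h,
      module = rep(names(module_sizes), times = module_sizes)
    ) |>
      dplyr::group_by(.data$module) |>
      dplyr::mutate(idx = dplyr::row_number()) |>
      dplyr::ungroup() |>
      # preserve the given module order, not alphabetical
      dplyr::arrange(match(.data$module, names(module_sizes)), .data$idx)
  }
  dplyr::bind_rows(one_hemi("L"), one_hemi("R")) |>
    dplyr::mutate(
      node = sprintf("%s_%s_%02d", .data$module, .data$hemisphere, .data$idx),
      system = unname(system_map[.data$module])
    ) |>
    dplyr::select("node", "hemisphere", "module", "system")
}

#' Default module sizes per hemisphere
#'
#' Six modules over 43 nodes per hemisphere, sized so that the association
#' system (Prefrontal, Lateral, Medial) holds 44 nodes in total and the
#' sensory system (Somatomotor, Visual, Auditory) 42, matching the standard
#' 86-node cortical parcellation this package emulates.
#' @return Named integer vector of per-hemisphere node counts.
#' @export
default_module_sizes <- function() {
  c(PF = 8L, LAT = 8L, SM = 9L, VIS = 7L, MED = 6L, AUD = 5L)
}

#' Default module-to-system assignment
#' @return Named character vector mapping modules to systems.
#' @export
default_system_map <- function() {
  c(
    PF = "association", LAT = "association", MED = "association",
    SM = "sensory", VIS = "sensory", AUD = "sensory"
  )
}

#' Canonical edge table of a parcellation
#'
#' Enumerates the upper triangle of the node-by-node matrix in row-major order
#' (node pairs `(1,2), (1,3), ..., (2,3), ...` over the canonical node order).
#' This single fixed ordering is what makes edge indices comparable across
#' connectomes, edge statistics and CPM selections.
#'
#' @param parcellation A parcellation tibble from [make_parcellation()].
#' @return A tibble with columns `edge` (1-based canonical index), `node_a`,
#'   `node_b`, `module_a`, `module_b`, `system_a`, `system_b`, and
#'   `category` (one of `"A:A"`, `"A:S"`, `"S:S"`).
#' @export
edge_table <- function(parcellation) {
  n <- nrow(parcellation)
  if (n < 2) stop("parcellation must contain at least 2 nodes")
  ij <- upper_pairs(n)
  sys_code <- ifelse(parcellation$system == "association", "A", "S")
  a <- ij[, 1]
  b <- ij[, 2]
  tibble::tibble(
    edge = seq_len(nrow(ij)),
    node_a = parcellation$node[a],
    node_b = parcellation$node[b],
    module_a = parcellation$module[a],
    module_b = parcellation$module[b],
    system_a = parcellation$system[a],
    system_b = parcellation$system[b],
    category = paste(pmin(sys_code[a], sys_code[b]),
      pmax(sys_code[a], sys_code[b]),
      sep = ":"
    )
  )
}

# row-major upper-triangle index pairs (i < j) for an n-node matrix
upper_pairs <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  unname(ij)
}

#' Number of edges of an n-node connectome
#' @param n_nodes Node count.
#' @return `n_nodes * (n_nodes - 1) / 2`.
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

#' Convert a symmetric matrix to its canonical edge vector
#'
#' @param m Symmetric numeric matrix.
#' @return Numeric vector of length `n(n-1)/2` in canonical edge order.
#' @seealso [edges_to_matrix()] for the exact inverse.
#' @export
matrix_to_edges <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ij <- upper_pairs(nrow(m))
  m[ij]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' @param edges Numeric edge vector.
#' @param node_names Optional dimnames for the matrix.
#' @return Symmetric matrix with zero diagonal; exact round trip with
#'   [matrix_to_edges()].
#' @export
edges_to_matrix <- function(edges, node_names = NULL) {
  n <- (1 + sqrt(1 + 8 * length(edges))) / 2
  if (n != round(n)) stop("edge vector length is not n(n-1)/2 for any integer n")
  n <- as.integer(n)
  m <- matrix(0, n, n)
  ij <- upper_pairs(n)
  m[ij] <- edges
  m[ij[, c(2, 1), drop = FALSE]] <- edges
  if (!is.null(node_names)) dimnames(m) <- list(node_names, node_names)
  m
}

#' Classify a set of edges by the systems of their endpoints
#'
#' Splits edges into association-association (`A:A`), association-sensory
#' (`A:S`) and sensory-sensory (`S:S`) categories, and reports the universe
#' size of each category in the parcellation, as used for the enrichment
#' proportion tests on CPM consensus edges.
#'
#' @param edges Integer vector of canonical edge indices (may be empty).
#' @param parcellation Parcellation tibble.
#' @return A tibble with columns `category`, `count` (edges from `edges` in the
#'   category) and `universe` (total edges of that category in the
#'   parcellation).
#' @export
categorize_edges <- function(edges, parcellation) {
  et <- edge_table(parcellation)
  if (length(edges) && (any(edges < 1) || any(edges > nrow(et)))) {
    stop("edge indices out of range for this parcellation")
  }
  lv <- c("A:A", "A:S", "S:S")
  tibble::tibble(category = lv) |>
    dplyr::left_join(
      et |>
        dplyr::mutate(selected = .data$edge %in% edges) |>
        dplyr::group_by(.data$category) |>
        dplyr::summarise(count = sum(.data$selected), universe = dplyr::n()),
      by = "category"
    ) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      universe = dplyr::coalesce(.data$universe, 0L)
    )
}
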