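#' Edgewise Spearman correlation with behaviour
#'
#' For every edge, the Spearman rank correlation between its values across
#' the training mice and the behavioural scores, with the two-sided
#' t-approximation p-value (standard at these sample sizes; an exact
#' permutation p is available for very small groups via `exact = TRUE`).
#'
#' @param edges Mice-by-edges matrix over training mice.
#' @param behavior Numeric behavioural score per training mouse.
#' @param exact Compute exact permutation p-values (feasible for n <= 10).
#' @return Tibble: `edge`, `rho`, `p`.
#' @export
edge_behavior_correlation <- function(edges, behavior, exact = FALSE) {
  stopifnot(is.matrix(edges), nrow(edges) == length(behavior))
  n <- nrow(edges)
  if (n < 4) stop("need at least 4 training mice")
  if (stats::sd(behavior) == 0) stop("behaviour is constant across training mice")
  rr <- apply(edges, 2, rank)
  rb <- rank(behavior)
  rho <- as.vector(stats::cor(rr, rb))
  if (exact) {
    if (n > 10) stop("exact permutation p only supported for n <= 10")
    perms <- permutations_of(n)
    p <- vapply(seq_along(rho), function(e) {
      null <- apply(perms, 1, function(pm) stats::cor(rr[pm, e], rb))
      mean(abs(null) >= abs(rho[e]) - 1e-12)
    }, numeric(1))
  } else {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(rho) >= 1] <- 0
  }
  tibble::tibble(edge = seq_along(rho), rho = rho, p = p)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Select positively and negatively predictive edges
#'
#' Edges whose Spearman correlation with behaviour is significant at
#' `alpha` (uncorrected), split by sign.
#'
#' @param correlations Tibble from [edge_behavior_correlation()].
#' @param alpha Per-edge selection threshold (default 0.05).
#' @return A list with integer vectors `positive` and `negative` (either may
#'   be empty).
#' @export
select_edges <- function(correlations, alpha = 0.05) {
  sig <- correlations$p < alpha
  list(
    positive = correlations$edge[sig & correlations$rho > 0],
    negative = correlations$edge[sig & correlations$rho < 0]
  )
}

#' Summed network strength over selected edges
#'
#' @param edge_values Numeric edge vector (one mouse's mean connectome).
#' @param positive,negative Integer edge sets (empty set sums to 0).
#' @return Named numeric vector `c(pos_sum, neg_sum)`.
#' @export
summarize_strength <- function(edge_values, positive, negative) {
  c(pos_sum = sum(edge_values[positive]), neg_sum = sum(edge_values[negative]))
}

# Precomputed per-fold quantities that do not depend on behaviour: training
# indices and the standardized column ranks of the training edge matrix.
# Reused across permutation shuffles, where only behaviour changes.
cpm_context <- function(edges) {
  n <- nrow(edges)
  folds <- lapply(seq_len(n), function(i) {
    train <- setdiff(seq_len(n), i)
    rr <- apply(edges[train, , drop = FALSE], 2, rank)
    rs <- scale(rr) # mean 0, sd 1 per edge column
    list(train = train, rank_std = rs)
  })
  list(n = n, folds = folds)
}

# Spearman rho of every edge with y over a fold's training mice, via the
# standardized-rank cross product; identical to cor(rank(x), rank(y)).
fold_rho <- function(fold, y) {
  ys <- as.vector(scale(rank(y)))
  as.vector(crossprod(fold$rank_std, ys)) / (length(y) - 1)
}

# selection on |rho| is equivalent to the two-sided t-approximation p < alpha
rho_critical <- function(n_train, alpha) {
  tc <- stats::qt(1 - alpha / 2, df = n_train - 2)
  tc / sqrt(n_train - 2 + tc^2)
}

# One full leave-one-out pass; returns predictions and per-fold edge sets.
cpm_engine <- function(edges, behavior, alpha, model, ctx) {
  n <- ctx$n
  rho_crit <- rho_critical(n - 1, alpha)
  predicted <- numeric(n)
  fold_sets <- vector("list", n)
  coefs <- vector("list", n)
  warn <- character()
  for (i in seq_len(n)) {
    fold <- ctx$folds[[i]]
    train <- fold$train
    rho <- fold_rho(fold, behavior[train])
    pos <- which(rho > rho_crit)
    neg <- which(rho < -rho_crit)
    fold_sets[[i]] <- list(positive = pos, negative = neg)
    if (length(pos) == 0 && length(neg) == 0) {
      predicted[i] <- mean(behavior[train])
      coefs[[i]] <- c(intercept = mean(behavior[train]), pos_sum = 0, neg_sum = 0)
      warn <- c(warn, sprintf("fold %d: no edges selected; predicting training mean", i))
      next
    }
    pos_sum <- if (length(pos)) rowSums(edges[train, pos, drop = FALSE]) else numeric(n - 1)
    neg_sum <- if (length(neg)) rowSums(edges[train, neg, drop = FALSE]) else numeric(n - 1)
    lo_pos <- sum(edges[i, pos])
    lo_neg <- sum(edges[i, neg])
    if (model == "two_predictor") {
      X <- cbind(intercept = 1, pos_sum = pos_sum, neg_sum = neg_sum)
      x_new <- c(1, lo_pos, lo_neg)
    } else {
      X <- cbind(intercept = 1, strength = pos_sum - neg_sum)
      x_new <- c(1, lo_pos - lo_neg)
    }
    fit <- stats::lm.fit(X, behavior[train])
    beta <- fit$coefficients
    if (anyNA(beta)) {
      warn <- c(warn, sprintf("fold %d: singular design; aliased terms dropped", i))
      beta[is.na(beta)] <- 0
    }
    predicted[i] <- sum(beta * x_new)
    coefs[[i]] <- beta
  }
  list(predicted = predicted, fold_sets = fold_sets, coefs = coefs,
       warnings = warn)
}

#' Connectome-based predictive modelling with leave-one-out cross-validation
#'
#' In each of the n folds, one mouse is held out; edges significantly
#' correlated (Spearman, `p < alpha` uncorrected, t-approximation) with
#' behaviour across the remaining mice are selected and summed into a
#' positive and a negative network-strength score per training mouse; a
#' least-squares regression of behaviour on the two scores (plus intercept)
#' is fitted and used to predict the held-out mouse. The result is scored as
#' the Pearson correlation between observed and predicted behaviour across
#' mice. Folds whose selection is empty (or whose design is singular) fall
#' back to predicting the training mean, with a logged warning in the result.
#'
#' @param edges Mice-by-edges matrix of session-averaged Fisher z values.
#' @param behavior Numeric behavioural score per mouse.
#' @param alpha Edge-selection threshold.
#' @param model `"two_predictor"` (default): behaviour ~ pos_sum + neg_sum;
#'   `"difference"`: behaviour ~ (pos_sum - neg_sum).
#' @return A `cpm_result` list: `predictions` tibble (`mouse`, `observed`,
#'   `predicted`), `r` (observed-vs-predicted Pearson), `folds` (per-fold
#'   edge sets and coefficients), `consensus` (edges selected in every fold,
#'   by sign), `warnings` (character).
#' @export
loocv_cpm <- function(edges, behavior, alpha = 0.05,
                      model = c("two_predictor", "difference")) {
  model <- match.arg(model)
  stopifnot(is.matrix(edges), nrow(edges) == length(behavior))
  n <- nrow(edges)
  if (n < 5) stop("LOOCV CPM requires at least 5 mice")
  mice <- rownames(edges) %||% paste0("mouse", seq_len(n))

  ctx <- cpm_context(edges)
  eng <- cpm_engine(edges, behavior, alpha, model, ctx)
  folds <- lapply(seq_len(n), function(i) {
    c(list(left_out = mice[i]), eng$fold_sets[[i]],
      list(coefficients = eng$coefs[[i]], prediction = eng$predicted[i]))
  })
  res <- list(
    predictions = tibble::tibble(mouse = mice, observed = behavior,
                                 predicted = eng$predicted),
    r = if (stats::sd(eng$predicted) == 0) 0 else stats::cor(behavior, eng$predicted),
    folds = folds,
    consensus = consensus_edges(folds),
    alpha = alpha, model = model,
    warnings = eng$warnings
  )
  class(res) <- "cpm_result"
  res
}

#' Permutation significance of a CPM prediction
#'
#' Reruns the full leave-one-out analysis on `n_shuffles` random
#' reassignments of the behavioural scores to mice and compares the observed
#' observed-vs-predicted correlation to the null distribution.
#'
#' @inheritParams loocv_cpm
#' @param n_shuffles Number of behaviour shuffles.
#' @param seed Integer seed.
#' @param convention `"add_one"`: `p = (1 + #\{null >= r\}) / (n_shuffles + 1)`;
#'   `"rank"`: `p = #\{null >= r\} / n_shuffles`.
#' @return A list: `observed` (the [loocv_cpm()] result), `null_r`
#'   (numeric vector), `p`.
#' @export
cpm_permutation <- function(edges, behavior, alpha = 0.05, n_shuffles = 1000,
                            seed = 1L, convention = c("add_one", "rank"),
                            model = c("two_predictor", "difference")) {
  convention <- match.arg(convention)
  model <- match.arg(model)
  observed <- loocv_cpm(edges, behavior, alpha, model)
  ctx <- cpm_context(edges)
  set.seed(seed)
  null_r <- vapply(seq_len(n_shuffles), function(b) {
    y <- sample(behavior)
    pred <- cpm_engine(edges, y, alpha, model, ctx)$predicted
    if (stats::sd(pred) == 0) 0 else stats::cor(y, pred)
  }, numeric(1))
  p <- if (convention == "add_one") {
    (1 + sum(null_r >= observed$r)) / (n_shuffles + 1)
  } else {
    sum(null_r >= observed$r) / n_shuffles
  }
  list(observed = observed, null_r = null_r, p = p, convention = convention)
}

#' Edges selected in every cross-validation fold
#'
#' @param folds List of fold records (each with `positive` and `negative`
#'   integer sets), as in a `cpm_result`.
#' @return A list with integer vectors `positive` and `negative`: the
#'   intersections across folds.
#' @export
consensus_edges <- function(folds) {
  stopifnot(length(folds) >= 1)
  list(
    positive = Reduce(intersect, lapply(folds, `[[`, "positive")),
    negative = Reduce(intersect, lapply(folds, `[[`, "negative"))
  )
}

#' Two-sample Z-test for independent proportions
#'
#' Pooled-proportion two-sided Z-test, used to compare the share of
#' consensus edges falling in each system category against another
#' category's share.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A list: `z`, `p` (two-sided), and the two sample proportions.
#' @export
proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(list(z = 0, p = 1, p1 = p1, p2 = p2,
                note = "degenerate pooled proportion"))
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Category enrichment of a consensus edge set
#'
#' Pairwise two-proportion Z-tests between the A:A, A:S and S:S shares of an
#' edge set, BH-corrected.
#'
#' @param edges Integer canonical edge indices.
#' @param parcellation Parcellation tibble.
#' @return Tibble: `category_1`, `category_2`, counts, `z`, `p`, `p_adjusted`.
#' @export
category_enrichment <- function(edges, parcellation) {
  cats <- categorize_edges(edges, parcellation)
  pairs <- utils::combn(cats$category, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- cats[cats$category == pr[1], ]
    b <- cats[cats$category == pr[2], ]
    zt <- proportion_ztest(a$count, a$universe, b$count, b$universe)
    tibble::tibble(category_1 = pr[1], category_2 = pr[2],
                   k1 = a$count, n1 = a$universe, k2 = b$count, n2 = b$universe,
                   z = zt$z, p = zt$p)
  })
  dplyr::mutate(out, p_adjusted = bh_fdr(.data$p))
}
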