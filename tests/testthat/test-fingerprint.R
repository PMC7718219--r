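test_that("similarity matrix matches a direct Pearson + atanh oracle", {
  h1 <- rbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(4, 3, 2, 1))
  h2 <- rbind(c(1.1, 2.2, 2.9, 4.2), c(2, 1.5, 3.5, 3), c(3.8, 3.1, 2.2, 0.9))
  S <- similarity_matrix(h1, h2)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(unclass(S)[i, j], atanh(cor(h1[j, ], h2[i, ])), tolerance = 1e-12)
  }
  # identical halves: diagonal is the clipped maximum
  Sid <- similarity_matrix(h1, h1)
  expect_equal(unname(diag(Sid)), rep(atanh(1 - 1e-7), 3))
  # permuting mice permutes rows and columns consistently
  pm <- c(3, 1, 2)
  Sp <- similarity_matrix(h1[pm, ], h2[pm, ])
  expect_equal(unclass(Sp), unclass(S)[pm, pm], ignore_attr = TRUE)
  expect_error(similarity_matrix(rbind(c(1, 1, 1, 1), h1[-1, ]), h2), "constant")
})

test_that("similarity summaries average the combined row and column", {
  S <- matrix(0.2, 3, 3)
  diag(S) <- 0.9
  rownames(S) <- colnames(S) <- paste0("m", 1:3)
  class(S) <- c("similarity_matrix", class(S))
  sm <- summarize_similarity(S)
  expect_equal(sm$individual, rep(0.9, 3))
  expect_equal(sm$group, rep(0.2, 3))

  # hand-summed 3x3 oracle with distinct entries
  S2 <- matrix(c(1.0, 0.1, 0.2,
                 0.3, 1.1, 0.4,
                 0.5, 0.6, 1.2), 3, 3, byrow = TRUE)
  rownames(S2) <- colnames(S2) <- paste0("m", 1:3)
  class(S2) <- c("similarity_matrix", class(S2))
  sm2 <- summarize_similarity(S2)
  expect_equal(sm2$group[1], mean(c(0.1, 0.2, 0.3, 0.5)))
  expect_equal(sm2$group[2], mean(c(0.3, 0.4, 0.1, 0.6)))
  expect_equal(sm2$group[3], mean(c(0.5, 0.6, 0.2, 0.4)))

  expect_error(summarize_similarity(S2[1, 1, drop = FALSE]), "at least 2")
})

test_that("normalized individual effect follows the subtraction/division rule", {
  expect_equal(normalized_individual_effect(1, 1), 0)
  expect_equal(normalized_individual_effect(1.08, 0.9), 0.1667, tolerance = 1e-3)
  # parcel mode: negative inputs floor to 0.001, negative effects to 0
  expect_equal(normalized_individual_effect(1.0, 1.2, parcel_mode = TRUE), 0)
  expect_equal(normalized_individual_effect(-0.5, 0.0005, parcel_mode = TRUE),
               (0.001 - 0.0005) / 0.001)
  expect_error(normalized_individual_effect(0, 0.5), "undefined")
})

test_that("identification requires a strict diagonal maximum per direction", {
  D <- matrix(0.1, 4, 4)
  diag(D) <- 1
  rownames(D) <- colnames(D) <- paste0("m", 1:4)
  idr <- identification(D)
  expect_equal(idr$rate_column, 1)
  expect_equal(idr$rate_row, 1)
  worst <- -D
  expect_equal(identification(worst)$rate_column, 0)
  # ties count as failures
  tie <- matrix(1, 2, 2)
  expect_equal(identification(tie)$rate_column, 0)

  set.seed(15)
  for (rep in 1:120) {
    n <- sample(3:16, 1)
    S <- matrix(rnorm(n * n), n, n)
    got <- identification(S)
    orc <- oracle_identification(S)
    expect_equal(got$rate_column, unname(orc["rate_column"]))
    expect_equal(got$rate_row, unname(orc["rate_row"]))
  }
})

test_that("identity shuffling yields chance-level identification and valid p", {
  set.seed(3)
  n <- 12
  S <- matrix(rnorm(n * n), n, n)
  diag(S) <- diag(S) + 10 # make the observed rates perfect
  rownames(S) <- colnames(S) <- paste0("m", 1:n)
  nul <- identification_null(S, n_shuffles = 500, seed = 7)
  expect_equal(nul$rate_column, 1)
  # observed beats every shuffle: the +1/(N+1) convention
  expect_equal(nul$p_column, 1 / 501)
  expect_equal(identification_null(S, 500, seed = 7, convention = "rank")$p_column,
               0)
  # mean correct-identification count under shuffling ~ 1 (random matching)
  expect_equal(mean(nul$null_column) * n, 1, tolerance = 0.25)
  # fixed seed reproduces the null exactly
  nul2 <- identification_null(S, n_shuffles = 500, seed = 7)
  expect_identical(nul$null_column, nul2$null_column)
})

test_that("edge z-normalization and the product statistics match hand oracles", {
  v <- c(1, 3, 5, 7)
  zv <- znorm_edges(v)
  expect_equal(mean(zv), 0)
  expect_equal(sd(zv), 1)
  expect_equal(zv, (v - 4) / sd(v))
  expect_equal(znorm_edges(10 + 3 * v), zv) # affine invariance
  expect_error(znorm_edges(rep(2, 5)), "constant")

  # 2-mouse hand example against product-then-average enumeration
  h1 <- znorm_edges(rbind(c(1, 2, 3, 4, 0), c(4, 0, 1, 3, 2)))
  h2 <- znorm_edges(rbind(c(2, 1, 3, 5, 1), c(3, 1, 0, 4, 2)))
  orc <- oracle_phi_dp(h1, h2)
  expect_equal(group_consistency(h1, h2), orc$phi)
  expect_equal(differential_power(h1, h2), orc$dp)

  # identical halves per mouse: phi is a mean of squares, non-negative
  expect_true(all(group_consistency(h1, h1) >= 0))

  set.seed(44)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    E <- sample(4:20, 1)
    a <- znorm_edges(matrix(rnorm(n * E), n, E))
    b <- znorm_edges(matrix(rnorm(n * E), n, E))
    orc <- oracle_phi_dp(a, b)
    expect_equal(group_consistency(a, b), orc$phi)
    expect_equal(differential_power(a, b), orc$dp)
    expect_true(all(orc$dp >= 0 & orc$dp <= 1))
    # phi is symmetric in the halves; dp is invariant to relabeling mice
    expect_equal(group_consistency(b, a), orc$phi)
    pm <- sample(n)
    expect_equal(differential_power(a[pm, , drop = FALSE], b[pm, , drop = FALSE]),
                 orc$dp)
  }
})

test_that("dp centres on one half under exchangeable edges", {
  set.seed(60)
  a <- znorm_edges(matrix(rnorm(10 * 500), 10, 500))
  b <- znorm_edges(matrix(rnorm(10 * 500), 10, 500))
  expect_equal(mean(differential_power(a, b)), 0.5, tolerance = 0.04)
})

test_that("top-percentile selection uses strict exceedance", {
  p <- make_parcellation()
  set.seed(8)
  v <- rnorm(3655)
  top <- top_percentile_edges(v, p, pct = 99)
  # distinct values: ceiling arithmetic under the interpolation percentile
  expect_equal(length(top$edges), 37)
  expect_true(all(v[top$edges] > top$threshold))
  # uniform values: nothing strictly exceeds the percentile
  expect_length(top_percentile_edges(rep(1, 3655), p)$edges, 0)
  # fractions tabulate every module pair and bound in [0, 1]
  expect_equal(nrow(top$fractions), 6 * 7 / 2)
  expect_equal(sum(top$fractions$n_edges), 3655)
  expect_true(all(top$fractions$fraction >= 0 & top$fractions$fraction <= 1))

  # planted top decile recovers exactly at pct 90 (366 = #{edges above the
  # 90th interpolated percentile of 3655})
  v2 <- runif(3655)
  hot <- sample(3655, 366)
  v2[hot] <- v2[hot] + 10
  expect_setequal(top_percentile_edges(v2, p, pct = 90)$edges, hot)
})

test_that("parcel-level similarity localises a noisy parcel", {
  set.seed(23)
  spec <- tiny_cohort_spec(n_mice = 6, seed = 77, sigma_individual = 0.3,
                           sigma_session = 0.05)
  co <- sample_cohort(spec)
  hv <- cohort_halves(co)
  mats1 <- lapply(1:6, function(m) edges_to_matrix(hv$h1[m, ], co$parcellation$node))
  mats2 <- lapply(1:6, function(m) edges_to_matrix(hv$h2[m, ], co$parcellation$node))
  ps <- parcel_similarity(mats1, mats2, co$parcellation)
  expect_equal(nrow(ps), 12)
  expect_false(any(ps$flagged))

  # identical halves: every parcel at the clipped maximum
  ps_id <- parcel_similarity(mats1, mats1, co$parcellation)
  expect_equal(ps_id$individual, rep(atanh(1 - 1e-7), 12))

  # scramble node 5's profile in the second half only: lowest similarity there
  mats2_noisy <- lapply(mats2, function(m) {
    m[5, -5] <- rnorm(11, 0, 2)
    m[-5, 5] <- m[5, -5]
    m
  })
  ps_n <- parcel_similarity(mats1, mats2_noisy, co$parcellation)
  expect_equal(which.min(ps_n$individual), 5L)

  # hemisphere averaging of mirrored values returns the common value
  ph <- parcel_similarity(mats1, mats2, co$parcellation, average_hemispheres = TRUE)
  expect_equal(nrow(ph), 6) # 12 nodes -> 6 (module, index) pairs
  left <- ps |> dplyr::left_join(co$parcellation, by = "node")
  manual <- tapply(ps$normalized_effect,
                   paste(left$module, sub(".*_(\\d+)$", "\\1", ps$node)), mean)
  expect_setequal(round(ph$normalized_effect, 12),
                  round(unname(as.vector(manual)), 12))
})

test_that("hierarchy correlation reproduces rank-formula results", {
  eff <- tibble::tibble(node = letters[1:5], effect = c(0.1, 0.4, 0.2, 0.5, 0.3))
  sc <- tibble::tibble(node = letters[1:5], score = c(1, 2, 3, 4, 5))
  hc <- hierarchy_correlation(eff, sc)
  expect_equal(hc$rho, cor(eff$effect, sc$score, method = "spearman"))
  # perfect and reversed ranks
  sc2 <- tibble::tibble(node = letters[1:5], score = eff$effect)
  expect_equal(hierarchy_correlation(eff, sc2)$rho, 1)
  sc3 <- tibble::tibble(node = letters[1:5], score = -eff$effect)
  expect_equal(hierarchy_correlation(eff, sc3)$rho, -1)
  expect_error(hierarchy_correlation(eff, sc[1:4, ]), "unmatched")
})

test_that("session subsampling enumerates the documented combination counts", {
  spec <- tiny_cohort_spec(n_mice = 5, seed = 19)
  co <- sample_cohort(spec)
  ss1 <- session_subsample(co$sessions, 1)
  ss2 <- session_subsample(co$sessions, 2)
  ss3 <- session_subsample(co$sessions, 3)
  expect_equal(ss1$n_combinations, 15)
  expect_equal(ss2$n_combinations, 45)
  expect_equal(ss3$n_combinations, 10)
  # the ordered convention doubles only the complementary k = 3 pairs
  expect_equal(session_subsample(co$sessions, 1, "ordered")$n_combinations, 15)
  expect_equal(session_subsample(co$sessions, 2, "ordered")$n_combinations, 45)
  expect_equal(session_subsample(co$sessions, 3, "ordered")$n_combinations, 20)
  expect_error(session_subsample(co$sessions, 4), "k must be")

  # k = 3 with halves {1,2,3}/{4,5,6} appears among the combinations and the
  # per-mouse average over the 10 combinations is finite and sane
  expect_equal(nrow(ss3$similarity), 5)
  expect_true(all(is.finite(ss3$similarity$individual)))
  expect_equal(nrow(ss3$rates), 10)
})
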