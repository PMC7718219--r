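test_that("edgewise Spearman correlations match the rank oracle", {
  set.seed(71)
  n <- 17
  edges <- matrix(rnorm(n * 12), n, 12)
  y <- rnorm(n)
  ct <- edge_behavior_correlation(edges, y)
  for (e in c(1, 5, 12)) {
    expect_equal(ct$rho[e], cor(edges[, e], y, method = "spearman"))
    st <- suppressWarnings(cor.test(edges[, e], y, method = "spearman",
                                    exact = FALSE))
    expect_equal(ct$p[e], st$p.value, tolerance = 1e-10)
  }
  # rank-identical and anti-ranked edges
  edges2 <- cbind(rank(y), -rank(y))
  ct2 <- edge_behavior_correlation(cbind(edges2, edges), y)
  expect_equal(ct2$rho[1], 1)
  expect_equal(ct2$rho[2], -1)
  expect_equal(ct2$p[1], 0)
  expect_error(edge_behavior_correlation(edges, rep(1, n)), "constant")
  expect_error(edge_behavior_correlation(edges[1:3, ], y[1:3]), "at least 4")

  # exact permutation p agrees with the t-approximation in direction
  small <- matrix(rnorm(6 * 3), 6, 3)
  ys <- rnorm(6)
  ex <- edge_behavior_correlation(small, ys, exact = TRUE)
  expect_true(all(ex$p >= 0 & ex$p <= 1))
})

test_that("edge selection splits significant correlations by sign", {
  ct <- tibble::tibble(edge = 1:4, rho = c(0.9, -0.8, 0.1, 0),
                       p = c(0.01, 0.02, 0.9, 1))
  sel <- select_edges(ct, alpha = 0.05)
  expect_equal(sel$positive, 1L)
  expect_equal(sel$negative, 2L)
  # zero-correlation edges are never selected
  none <- select_edges(tibble::tibble(edge = 1, rho = 0, p = 0.001))
  expect_length(none$positive, 0)
  expect_length(none$negative, 0)
})

test_that("strength summaries sum selected edges, empty sets to zero", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(summarize_strength(v, integer(), integer()),
               c(pos_sum = 0, neg_sum = 0))
  expect_equal(summarize_strength(v, 3L, integer())[["pos_sum"]], 3)
  expect_equal(summarize_strength(v, c(1L, 4L), c(2L, 5L)),
               c(pos_sum = 5, neg_sum = 7))
})

test_that("LOOCV recovers a noiseless planted linear signal", {
  spec <- cohort_spec(
    n_mice = 18, n_sessions = 6, n_runs_per_session = 1, n_frames_per_run = 198,
    parcellation = tiny_parcellation(6), sigma_session = 0.05,
    behavior_spec = behavior_spec(planted_edges = c(2, 10, 20), beta = 100,
                                  noise_sd = 0, shared_sd = 0.5),
    seed = 55
  )
  co <- sample_cohort(spec)
  cpm <- loocv_cpm(cohort_mean_edges(co), co$behavior$mean_latency_s)
  expect_length(cpm$folds, 18)
  expect_gt(cpm$r, 0.95)
  expect_true(all(c(2, 10, 20) %in% cpm$consensus$positive))

  # consensus sets are contained in every fold's sets
  for (f in cpm$folds) {
    expect_true(all(cpm$consensus$positive %in% f$positive))
    expect_true(all(cpm$consensus$negative %in% f$negative))
  }

  # per-fold selections agree with the standalone correlation + selection path
  i <- 7
  train <- setdiff(1:18, i)
  edges <- cohort_mean_edges(co)
  sel <- select_edges(
    edge_behavior_correlation(edges[train, ], co$behavior$mean_latency_s[train]),
    alpha = 0.05
  )
  expect_equal(cpm$folds[[i]]$positive, sel$positive)
  expect_equal(cpm$folds[[i]]$negative, sel$negative)
})

test_that("predictions never use the left-out mouse (no leakage)", {
  spec <- tiny_cohort_spec(n_mice = 8, seed = 91)
  co <- sample_cohort(spec)
  edges <- cohort_mean_edges(co)
  y <- co$behavior$mean_latency_s
  base <- loocv_cpm(edges, y)
  y2 <- y
  y2[3] <- y2[3] + 500 # perturb only the held-out mouse's behaviour
  pert <- loocv_cpm(edges, y2)
  expect_equal(pert$folds[[3]]$prediction, base$folds[[3]]$prediction)
})

test_that("shuffled behaviour yields null-centred predictions and uniform-ish p", {
  spec <- tiny_cohort_spec(n_mice = 10, seed = 17)
  co <- sample_cohort(spec)
  edges <- cohort_mean_edges(co)
  set.seed(2)
  rs <- replicate(30, loocv_cpm(edges, sample(co$behavior$mean_latency_s))$r)
  expect_lt(abs(mean(rs)), 0.25)

  # permutation machinery: determinism and the two p conventions
  pm <- cpm_permutation(edges, co$behavior$mean_latency_s, n_shuffles = 50,
                        seed = 4)
  pm2 <- cpm_permutation(edges, co$behavior$mean_latency_s, n_shuffles = 50,
                         seed = 4)
  expect_identical(pm$null_r, pm2$null_r)
  expect_equal(pm$p, (1 + sum(pm$null_r >= pm$observed$r)) / 51)
  pr <- cpm_permutation(edges, co$behavior$mean_latency_s, n_shuffles = 50,
                        seed = 4, convention = "rank")
  expect_equal(pr$p, sum(pr$null_r >= pr$observed$r) / 50)

  # the fast permutation engine equals a literal LOOCV rerun on shuffled data
  set.seed(4)
  y_first <- sample(co$behavior$mean_latency_s)
  expect_equal(pm$null_r[1], loocv_cpm(edges, y_first)$r)
})

test_that("empty-selection folds fall back to the training mean with a log", {
  set.seed(12)
  edges <- matrix(rnorm(6 * 5, sd = 1e-3), 6, 5)
  y <- rnorm(6)
  # with 5 near-noise edges some folds select nothing: prediction = train mean
  res <- loocv_cpm(edges, y, alpha = 1e-6)
  expect_true(length(res$warnings) > 0)
  expect_equal(res$folds[[1]]$prediction, mean(y[-1]))
})

test_that("consensus edges equal the set-intersection oracle", {
  set.seed(81)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    folds <- lapply(seq_len(k), function(i) {
      list(positive = sample(20, sample(0:10, 1)),
           negative = sample(20, sample(0:10, 1)))
    })
    cons <- consensus_edges(folds)
    expect_setequal(cons$positive,
                    oracle_consensus(lapply(folds, `[[`, "positive")))
    expect_setequal(cons$negative,
                    oracle_consensus(lapply(folds, `[[`, "negative")))
  }
  one <- list(list(positive = c(1L, 2L), negative = 3L))
  expect_equal(consensus_edges(one)$positive, c(1L, 2L))
})

test_that("proportion Z-test matches the pooled-variance textbook formula", {
  zt <- proportion_ztest(30, 100, 10, 100)
  pooled <- 40 / 200
  z_hand <- (0.3 - 0.1) / sqrt(pooled * (1 - pooled) * (1 / 100 + 1 / 100))
  expect_equal(zt$z, z_hand)
  expect_equal(zt$p, 2 * pnorm(-abs(z_hand)))
  # equal proportions: Z = 0, p = 1
  eq <- proportion_ztest(5, 50, 10, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # swapping groups negates Z, p unchanged
  sw <- proportion_ztest(10, 100, 30, 100)
  expect_equal(sw$z, -zt$z)
  expect_equal(sw$p, zt$p)
  # degenerate pooled proportion
  dg <- proportion_ztest(0, 10, 0, 20)
  expect_equal(dg$z, 0)
  expect_equal(dg$p, 1)
  expect_error(proportion_ztest(5, 0, 1, 10), "positive")
  expect_error(proportion_ztest(11, 10, 1, 10), "0 <= k <= n")
})

test_that("category enrichment reports BH-corrected pairwise tests", {
  p <- make_parcellation()
  et <- edge_table(p)
  ss <- et$edge[et$category == "S:S"][1:50] # strongly S:S-biased set
  enr <- category_enrichment(ss, p)
  expect_equal(nrow(enr), 3)
  expect_true(all(enr$p_adjusted >= enr$p))
  ss_vs <- enr[enr$category_1 == "A:A" & enr$category_2 == "S:S", ]
  expect_lt(ss_vs$z, 0) # A:A share below S:S share
})
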