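ring_connectome <- function(n) {
  ids <- sprintf("r%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    W[i, j] <- W[j, i] <- 1
  }
  make_connectome(W)
}

test_that("symmetric graphs give the forced uniform score", {
  cn <- ring_connectome(7)
  for (d in c(0.05, 0.15, 0.5)) {
    expect_equal(unname(pagerank_scores(cn, d = d)), rep(1 / 7, 7),
                 tolerance = 1e-10)
  }
  # d = 1 is the teleport-only limit: uniform on any graph
  cn2 <- random_connectome(9, seed = 17)
  expect_equal(unname(pagerank_scores(cn2, d = 1)), rep(1 / 9, 9))
})

test_that("a 4-node star matches the naive fixed-point oracle", {
  ids <- c("hub", "s1", "s2", "s3")
  W <- matrix(0, 4, 4, dimnames = list(ids, ids))
  W["hub", c("s1", "s2", "s3")] <- 1
  W[c("s1", "s2", "s3"), "hub"] <- 1
  cn <- make_connectome(W)
  got <- pagerank_scores(cn, d = 0.15)
  want <- pr_oracle(W, d = 0.15)
  expect_equal(got, want, tolerance = 1e-10)
  expect_gt(got["hub"], got["s1"])
})

test_that("scores match the oracle and igraph on random graphs", {
  for (seed in 1:8) {
    set.seed(seed)
    cn <- random_connectome(sample(5:14, 1), p = 0.5, seed = seed + 500)
    got <- pagerank_scores(cn)
    expect_equal(got, pr_oracle(cn$weights), tolerance = 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-9)
    # with the teleport term damped by d, d = 0.15 is standard
    # 0.85-damped PageRank; cross-check against igraph on the arc graph
    # (only without isolates, whose dangling handling is ours to define)
    if (all(rowSums(cn$weights > 0) > 0)) {
      g <- igraph::graph_from_adjacency_matrix((cn$weights > 0) * 1,
                                               mode = "directed")
      ig <- igraph::page_rank(g, damping = 0.85)$vector
      expect_equal(unname(got), unname(ig), tolerance = 1e-8)
    }
  }
})

test_that("dangling isolates get teleport mass and keep normalization", {
  ids <- c("a", "b", "iso")
  W <- matrix(0, 3, 3, dimnames = list(ids, ids))
  W["a", "b"] <- W["b", "a"] <- 2
  cn <- make_connectome(W)
  got <- pagerank_scores(cn, d = 0.15)
  expect_equal(sum(got), 1, tolerance = 1e-9)
  expect_equal(got, pr_oracle(W), tolerance = 1e-10)
  expect_lt(got["iso"], got["a"])
})

test_that("hemisphere ranking is deterministic with lexicographic ties", {
  atlas <- atlas_topology(
    parcels = c("L_a", "L_b", "R_a", "R_b"),
    hemisphere = c(L_a = "left", L_b = "left", R_a = "right", R_b = "right"),
    lobe = c(L_a = "x/left", L_b = "x/left", R_a = "x/right",
             R_b = "x/right"),
    resectable = rep(TRUE, 4),
    adjacency = rbind(c("L_a", "L_b"), c("R_a", "R_b"), c("L_a", "R_a"))
  )
  scores <- c(L_a = 0.3, L_b = 0.2, R_a = 0.25, R_b = 0.25)
  r <- rank_per_hemisphere(scores, atlas)
  expect_equal(r$rank_hemisphere[r$parcel == "L_a"], 1L)
  expect_equal(r$rank_hemisphere[r$parcel == "L_b"], 2L)
  # exact tie on the right: R_a outranks R_b lexicographically
  expect_equal(r$rank_hemisphere[r$parcel == "R_a"], 1L)
  expect_equal(r$rank_hemisphere[r$parcel == "R_b"], 2L)
  expect_equal(r$rank_overall[r$parcel == "L_a"], 1L)
  # permuting the score vector leaves ranks unchanged
  r2 <- rank_per_hemisphere(scores[c(3, 1, 4, 2)], atlas)
  expect_equal(r2, r)
  expect_error(rank_per_hemisphere(scores[1:3], atlas), "missing")
})

test_that("prediction rates are nested and perfect when PR finds the worst", {
  atlas <- recovery_atlas()
  lobe <- "lobeA/left"
  sets1 <- enumerate_resections(atlas, lobe, max_size = 1)
  cfg <- cohort_config(atlas, n_subjects = 5, total_streamlines = 5e4,
                       seed = 21)
  cohort <- generate_cohort(cfg)
  sweeps <- lapply(cohort$connectomes, percolation_sweep, sets = sets1)
  # rigged scores: top PR parcel is exactly each subject's worst deletion
  rigged <- lapply(sweeps, function(sw) {
    singles <- sw$records[sw$records$size == 1L, ]
    worst <- singles$parcels[which.min(singles$ge)]
    s <- stats::setNames(rep(1 / 18, 18), atlas$parcels)
    s[worst] <- s[worst] * 2
    s / sum(s)
  })
  rates <- pr_prediction_rates(sweeps, rigged, atlas, lobe)
  expect_equal(rates$rate_worst, 1)
  expect_equal(rates$rate_worst_or_neighbor, 1)
  expect_equal(rates$rate_top3, 1)
  expect_equal(rates$label_worst, "5/5; 100%")

  # genuine PageRank: criteria remain nested
  scores <- lapply(cohort$connectomes, pagerank_scores)
  rates2 <- pr_prediction_rates(sweeps, scores, atlas, lobe)
  expect_lte(rates2$rate_worst, rates2$rate_worst_or_neighbor)
  expect_gte(rates2$rate_top3, 0)
  expect_lte(rates2$rate_top3, 1)
})

test_that("weighted-transition PageRank tracks the planted epicenter", {
  # synthetic connectomes at this scale are dense (every pair positive), so
  # the unweighted arc graph is complete and degree-based PageRank is
  # uniform; the streamline-weighted variant must find the planted hub far
  # above the 1/9 chance level
  atlas <- recovery_atlas()
  lobe <- "lobeA/left"
  sets1 <- enumerate_resections(atlas, lobe, max_size = 1)
  hits <- logical(0)
  for (i in 1:5) {
    cohort <- generate_cohort(cohort_config(atlas, n_subjects = 10,
                                            seed = 800 + i))
    sweeps <- lapply(cohort$connectomes, percolation_sweep, sets = sets1)
    scores <- lapply(cohort$connectomes, pagerank_scores, weighted = TRUE)
    rates <- pr_prediction_rates(sweeps, scores, atlas, lobe)
    expect_lte(rates$rate_worst, rates$rate_worst_or_neighbor)
    hits <- c(hits, rates$rate_worst)
  }
  expect_gt(mean(hits), 3 / 9)
})

test_that("non-convergence is reported", {
  cn <- random_connectome(8, seed = 5)
  expect_error(pagerank_scores(cn, max_iter = 1L), "did not converge")
})
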