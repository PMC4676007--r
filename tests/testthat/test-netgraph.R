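# Graph construction, admissibility, outlier filtering, and the binary
# small-world statistics against brute-force oracles.

path4 <- function() {
  A <- matrix(FALSE, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- TRUE
  graph_from_adjacency(A | t(A))
}

test_that("percentile threshold keeps strictly-greater weights only", {
  w <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  M <- diag(4)
  M[upper.tri(M)] <- w
  M <- M + t(M); diag(M) <- 1
  g <- threshold_graph(M, 75)
  expect_equal(g$threshold_used, 0.525)
  expect_equal(nrow(g$edges), 1)
  expect_false(g$degenerate)
  # uniform matrix: zero edges, flagged degenerate
  U <- matrix(0.5, 4, 4); diag(U) <- 1
  gu <- threshold_graph(U, 75)
  expect_equal(nrow(gu$edges), 0)
  expect_true(gu$degenerate)
  # percentile 0 keeps every pair with weight above the minimum-interpolated
  # threshold, i.e. the complete graph for all-distinct positive weights
  g0 <- threshold_graph(M, 0)
  expect_equal(nrow(g0$edges), 6)
})

test_that("raising the percentile never adds an edge", {
  set.seed(11)
  for (i in 1:20) {
    M <- matrix(0, 8, 8)
    M[upper.tri(M)] <- runif(28)
    M <- M + t(M); diag(M) <- 1
    prev <- Inf
    for (p in c(0, 25, 50, 75, 90)) {
      ne <- nrow(threshold_graph(M, p)$edges)
      expect_lte(ne, prev)
      prev <- ne
    }
    # 75th percentile of distinct weights keeps about a quarter of pairs
    expect_lte(nrow(threshold_graph(M, 75)$edges), ceiling(0.25 * 28) + 1)
  }
})

test_that("admissibility requires (virtually) all nodes connected", {
  # 9 nodes, one isolated: 8/9 < 99%
  A <- matrix(FALSE, 9, 9)
  for (i in 1:7) A[i, i + 1] <- TRUE
  g <- graph_from_adjacency(A | t(A))
  expect_false(is_admissible_connectivity(g))
  # connected 18-node ring
  B <- matrix(FALSE, 18, 18)
  for (i in 1:17) B[i, i + 1] <- TRUE
  B[1, 18] <- TRUE
  expect_true(is_admissible_connectivity(graph_from_adjacency(B | t(B))))
  # edgeless graph
  expect_false(is_admissible_connectivity(
    graph_from_adjacency(matrix(FALSE, 3, 3))))
})

test_that("ensemble outlier filter removes tails of node/edge/density distributions", {
  ring <- function(n) {
    A <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) A[i, i + 1] <- TRUE
    A[1, n] <- TRUE
    graph_from_adjacency(A | t(A))
  }
  dense <- function(n) graph_from_adjacency(
    matrix(TRUE, n, n) & !diag(TRUE, n))
  # identical graphs: nothing removed
  ens <- replicate(100, ring(10), simplify = FALSE)
  out <- filter_outlier_graphs(ens)
  expect_length(out, 100)
  # one extreme edge-count outlier among 100
  ens2 <- c(replicate(99, ring(10), simplify = FALSE), list(dense(10)))
  out2 <- filter_outlier_graphs(ens2)
  expect_length(out2, 99)
  expect_equal(attr(out2, "removed_counts")[["edges"]], 1)
  # small ensembles pass through with a warning
  expect_warning(out3 <- filter_outlier_graphs(ens[1:10]), "skipped")
  expect_length(out3, 10)
  # never removes more than the percentile tails can cover
  set.seed(13)
  ens4 <- replicate(200, graph_from_adjacency(random_adjacency(12, runif(1, 0.2, 0.6))),
                    simplify = FALSE)
  out4 <- filter_outlier_graphs(ens4)
  expect_lte(attr(out4, "n_removed"), 0.2 * 3 * 200)
})

test_that("clustering coefficient matches hand-derived cases", {
  K4 <- graph_from_adjacency(matrix(TRUE, 4, 4) & !diag(TRUE, 4))
  expect_equal(clustering_coefficient(K4)$mean, 1)
  expect_equal(clustering_coefficient(path4())$mean, 0)
  # square with one chord: per-node (2/3, 1, 2/3, 1)
  A <- matrix(FALSE, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[1, 4] <- A[1, 3] <- TRUE
  g <- graph_from_adjacency(A | t(A))
  expect_equal(clustering_coefficient(g)$per_node, c(2 / 3, 1, 2 / 3, 1))
  expect_equal(clustering_coefficient(g)$mean, 5 / 6)
})

test_that("characteristic path length matches hand-derived cases", {
  K5 <- graph_from_adjacency(matrix(TRUE, 5, 5) & !diag(TRUE, 5))
  expect_equal(characteristic_path_length(K5)$L, 1)
  expect_equal(characteristic_path_length(path4())$L, 5 / 3)
  ring5 <- matrix(FALSE, 5, 5)
  for (i in 1:4) ring5[i, i + 1] <- TRUE
  ring5[1, 5] <- TRUE
  expect_equal(characteristic_path_length(
    graph_from_adjacency(ring5 | t(ring5)))$L, 1.5)
  # edgeless graph: L undefined
  g0 <- graph_from_adjacency(matrix(FALSE, 3, 3))
  expect_true(is.na(characteristic_path_length(g0)$L))
  expect_equal(characteristic_path_length(g0)$n_unreachable_pairs, 3)
})

test_that("betweenness centrality matches hand-derived cases", {
  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- TRUE
  g <- graph_from_adjacency(star | t(star))
  expect_equal(betweenness_centrality(g), c(1, 0, 0, 0, 0))
  K4 <- graph_from_adjacency(matrix(TRUE, 4, 4) & !diag(TRUE, 4))
  expect_equal(betweenness_centrality(K4), rep(0, 4))
  expect_equal(betweenness_centrality(path4()), c(0, 2 / 3, 2 / 3, 0))
})

test_that("graph statistics agree with brute-force oracles on random graphs", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:14, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.7))
    g <- graph_from_adjacency(A)
    expect_equal(clustering_coefficient(g)$per_node,
                 oracle_clustering(A)$per_node)
    expect_equal(characteristic_path_length(g)$L, oracle_charpath(A)$L)
  }
  for (i in 1:15) {
    n <- sample(4:7, 1)
    A <- random_adjacency(n, runif(1, 0.25, 0.7))
    expect_equal(betweenness_centrality(graph_from_adjacency(A)),
                 oracle_betweenness(A))
  }
})

test_that("ensemble statistics aggregate per-graph values exactly", {
  K4 <- graph_from_adjacency(matrix(TRUE, 4, 4) & !diag(TRUE, 4))
  ens <- replicate(5, K4, simplify = FALSE)
  st <- ensemble_stats(ens)
  expect_equal(st$C, rep(1, 5))
  expect_equal(st$L, rep(1, 5))
  expect_equal(mean(st$C), 1)
  expect_equal(sd(st$C), 0)
  mixed <- list(K4, path4())
  stm <- ensemble_stats(mixed)
  expect_equal(mean(stm$C), mean(c(1, 0)))
  expect_error(ensemble_stats(list()), class = "plvnet_empty_ensemble")
})

test_that("modular coupling yields higher clustering than uniform coupling", {
  # identical natural frequencies isolate the coupling topology: the only
  # difference between conditions is whether coupling is concentrated
  # within two blocks or spread evenly over all pairs
  m <- 18
  blk <- rep(1:2, each = 9)
  Km <- matrix(0, m, m)
  Km[blk == 1, blk == 1] <- 6
  Km[blk == 2, blk == 2] <- 6
  diag(Km) <- 0
  Ku <- matrix(1, m, m)
  diag(Ku) <- 0
  mean_C <- function(K, seed) {
    cfg <- synth_config(n_channels_per_region = 9, duration = 10,
                        natural_freqs = rep(11, m), coupling = K,
                        phase_noise_sd = 1.5, obs_noise_sd = 0, seed = seed)
    arr <- windowed_plv(synth_lfp(simulate_phases(cfg), cfg), cfg$fs)
    mean(apply(arr, 3, function(M)
      clustering_coefficient(threshold_graph(M))$mean))
  }
  diffs <- vapply(1:20, function(s) mean_C(Km, s) - mean_C(Ku, 500 + s),
                  numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(mean(diffs > 0), 0.8)
})
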