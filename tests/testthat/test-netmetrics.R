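test_that("sparsity binarization keeps the rounded count of strongest positive edges", {
  set.seed(2)
  z <- edges_to_mat(rnorm(91), 14)
  a20 <- binarize_sparsity(z, 0.2)
  expect_equal(attr(a20, "n_kept"), 18)  # round(0.2 * 91) = 18
  a30 <- binarize_sparsity(z, 0.3)
  expect_equal(attr(a30, "n_kept"), 27)  # round(0.3 * 91) = 27
  expect_true(all(a20 %in% 0:1))
  expect_equal(a20, t(a20))
  expect_equal(diag(a20), rep(0L, 14), ignore_attr = TRUE)

  # kept edges are exactly the largest positive ones
  ev <- mat_to_edges(z)
  kept <- mat_to_edges(a20) == 1
  expect_true(min(ev[kept]) >= max(ev[!kept & ev > 0][
    rank(-ev[!kept & ev > 0]) <= 0], -Inf))
  expect_equal(sum(kept), 18)
  expect_true(all(sort(ev[kept], decreasing = TRUE) ==
                    sort(ev, decreasing = TRUE)[1:18]))

  # all-negative matrix: empty graph with a warning
  expect_warning(an <- binarize_sparsity(-abs(z), 0.2), "empty")
  expect_equal(sum(an), 0)

  # scale invariance: doubling values changes nothing (rank-based)
  expect_equal(binarize_sparsity(2 * z, 0.25), binarize_sparsity(z, 0.25),
               ignore_attr = TRUE)
})

test_that("global metrics match closed forms on canonical graphs", {
  K5 <- matrix(1, 5, 5) - diag(5)
  m <- global_metrics(K5)
  expect_equal(unlist(m[c("E_glob", "E_loc", "C_p", "L_p")]),
               c(E_glob = 1, E_loc = 1, C_p = 1, L_p = 1))

  P3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  m3 <- global_metrics(P3)
  expect_equal(m3$E_glob, (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(m3$C_p, 0)
  expect_equal(m3$L_p, 4 / 3, tolerance = 1e-12)

  # disconnected pair handling
  two <- matrix(0, 3, 3); two[1, 2] <- two[2, 1] <- 1
  m2 <- global_metrics(two)
  expect_equal(m2$n_disconnected_pairs, 2)
  expect_equal(m2$L_p, 1)  # mean over connected pairs only
  expect_equal(m2$E_glob, 2 / 6, tolerance = 1e-12)
})

test_that("metrics equal brute force on every small graph and random 14-node graphs", {
  # exhaustive over all graphs with 4 nodes, all with 5 nodes sampled densely
  for (n in 3:4) {
    E <- n * (n - 1) / 2
    for (code in 0:(2^E - 1)) {
      ev <- as.integer(intToBits(code)[1:E])
      adj <- edges_to_mat(ev, n)
      got <- global_metrics(adj)
      want <- bf_metrics(adj)
      for (f in names(want))
        expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    }
  }
  set.seed(6)
  for (code in sample(0:(2^10 - 1), 200)) {
    ev <- as.integer(intToBits(code)[1:10])
    adj <- edges_to_mat(ev, 5)
    got <- global_metrics(adj)
    want <- bf_metrics(adj)
    for (f in names(want)) expect_equal(got[[f]], want[[f]],
                                        tolerance = 1e-12)
  }
  for (i in 1:50) {
    adj <- random_adj(14, runif(1, 0.1, 0.5), seed = 100 + i)
    got <- global_metrics(adj)
    want <- bf_metrics(adj)
    for (f in names(want)) expect_equal(got[[f]], want[[f]],
                                        tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on random graphs", {
  for (i in 1:20) {
    adj <- random_adj(12, 0.3, seed = 200 + i)
    g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
    got <- global_metrics(adj)
    expect_equal(got$E_glob, igraph::global_efficiency(g), tolerance = 1e-12)
    expect_equal(got$C_p,
                 mean(igraph::transitivity(g, type = "localundirected",
                                           isolates = "zero")),
                 tolerance = 1e-12)
    if (igraph::is_connected(g))
      expect_equal(got$L_p, igraph::mean_distance(g), tolerance = 1e-12)
  }
})

test_that("degree-preserving nulls give gamma = lambda = 1 on rewiring-invariant graphs and sigma > 1 on small-world lattices", {
  K6 <- matrix(1, 6, 6) - diag(6)
  nm <- normalized_metrics(K6, n_null = 20, seed = 1)
  expect_equal(nm$gamma, 1)
  expect_equal(nm$lambda_norm, 1)
  expect_equal(nm$sigma_sw, 1)

  # null ensembles preserve the degree sequence by construction
  adj <- random_adj(14, 0.3, seed = 3)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  set.seed(4)
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 100))
  expect_equal(sort(igraph::degree(gr)), sort(igraph::degree(g)))

  # ring lattice with light rewiring is small-world: sigma > 1 usually
  ring <- function(n, k) {
    a <- matrix(0L, n, n)
    for (d in 1:(k / 2)) for (i in 1:n) {
      j <- ((i + d - 1) %% n) + 1
      a[i, j] <- a[j, i] <- 1L
    }
    a
  }
  ws <- function(seed) {
    set.seed(seed)
    g <- igraph::graph_from_adjacency_matrix(ring(20, 4), mode = "undirected")
    g <- igraph::rewire(g, igraph::each_edge(p = 0.1))
    igraph::as_adjacency_matrix(g, sparse = FALSE)
  }
  sig <- vapply(1:40, function(s)
    normalized_metrics(ws(s), n_null = 30, seed = s)$sigma_sw, 0)
  expect_gte(mean(sig > 1), 0.95)

  # determinism given seed
  n1 <- normalized_metrics(adj, n_null = 10, seed = 9)
  n2 <- normalized_metrics(adj, n_null = 10, seed = 9)
  expect_identical(n1, n2)
  expect_equal(n1$sigma_sw, n1$gamma / n1$lambda_norm, tolerance = 1e-12)
})

test_that("AUC over the sparsity grid matches the trapezoid oracle", {
  grid <- sparsity_grid()
  expect_length(grid, 11)
  expect_equal(auc_over_grid(rep(3, 11), grid), 0.3, tolerance = 1e-12)
  expect_equal(auc_over_grid(seq(0, 1, length.out = 11), grid), 0.05,
               tolerance = 1e-12)
  set.seed(8)
  v <- runif(11)
  oracle <- sum(vapply(1:10, function(i)
    (v[i] + v[i + 1]) / 2 * (grid[i + 1] - grid[i]), 0))
  expect_equal(auc_over_grid(v, grid), oracle, tolerance = 1e-12)
  expect_error(auc_over_grid(c(v[-1], NA), grid), "non-finite")
})

test_that("windowed metric AUCs match per-window recomputation and variances behave", {
  set.seed(12)
  Z <- matrix(rnorm(8 * 91, sd = 0.5), 8, 91)
  grid <- sparsity_grid()
  out <- dynamic_metric_variance(Z, grid, n_nodes = 14)
  expect_equal(dim(out$auc), c(8, 4))
  # oracle: R-side loop over windows and thresholds
  for (w in c(1, 5)) {
    vals <- vapply(grid, function(S) {
      m <- global_metrics(binarize_sparsity(Z[w, ], S, n = 14))
      c(m$E_glob, m$E_loc, m$C_p, m$L_p)
    }, numeric(4))
    for (j in 1:4)
      expect_equal(out$auc[w, j], auc_over_grid(vals[j, ], grid),
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(out$variance, apply(out$auc, 2, var), tolerance = 1e-12)

  # identical windows: zero variance
  Zc <- Z[rep(1, 5), ]
  expect_equal(unname(dynamic_metric_variance(Zc, grid,
                                              n_nodes = 14)$variance),
               rep(0, 4))
  # scale invariance of rank-based thresholding
  expect_equal(dynamic_metric_variance(2 * Z, grid, n_nodes = 14)$auc,
               out$auc, tolerance = 1e-12)
})

test_that("E_glob is non-decreasing in sparsity for all-positive distinct edges", {
  set.seed(14)
  z <- edges_to_mat(runif(91, 0.1, 1), 14)
  vals <- vapply(sparsity_grid(0.05, 0.5, 0.05), function(S)
    global_metrics(binarize_sparsity(z, S))$E_glob, 0)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("a two-state scan has larger efficiency-AUC variance than a one-state scan", {
  # paired over seeds: switching between states with different positive-edge
  # density inflates variance over windows
  sp2 <- small_spec(k = 2, n_networks = 8, n_timepoints = 120, leave = 0.04)
  sp1 <- small_spec(k = 1, n_networks = 8, n_timepoints = 120)
  wins <- function(sp, seed) {
    sim <- simulate_subject(sp, "HC", seed)
    dynamic_fc(sim$tc, tapered_window_spec(20),
               glasso_config(penalty_grid = 0))
  }
  grid <- sparsity_grid()
  res <- vapply(1:8, function(s) {
    v2 <- dynamic_metric_variance(wins(sp2, s), grid)$variance["E_glob"]
    v1 <- dynamic_metric_variance(wins(sp1, s), grid)$variance["E_glob"]
    v2 > v1
  }, TRUE)
  expect_gte(mean(res), 0.7)
})
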