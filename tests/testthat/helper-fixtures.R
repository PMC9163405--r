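# Shared fixtures and independent oracles used across test files.

# small timecourse with reproducible Gaussian data
make_tc <- function(T_ = 60, n = 4, seed = 1, tr = 2) {
  set.seed(seed)
  timecourse(matrix(rnorm(T_ * n), T_, n), paste0("N", seq_len(n)), tr = tr)
}

# a compact 3-state spec on few networks for fast simulator tests
small_spec <- function(k = 2, n_networks = 5, n_timepoints = 120,
                       leave = 0.05, ...) {
  designs <- lapply(seq_len(k), function(s) {
    # state s couples a distinct pair block
    data.frame(i = 1 + (s - 1) %% (n_networks - 1),
               j = n_networks,
               value = 0.7 * (-1)^s)
  })
  P <- matrix(leave / (k - 1 + (k == 1)), k, k)
  diag(P) <- 1 - leave
  if (k == 1) P <- matrix(1, 1, 1)
  synth_spec(n_networks = n_networks, n_timepoints = n_timepoints,
             k_states = k, block_design = designs,
             transition_matrix_per_group = list(HD = P, NonD = P, HC = P),
             initial_distribution = rep(1 / k, k),
             edge_effects = list(), ...)
}

# brute-force graph metrics oracle: all-pairs BFS + direct neighborhood
# enumeration, independent of the compiled implementation
bf_bfs_dist <- function(adj, src) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer()
    for (v in frontier) {
      nb <- which(adj[v, ] != 0)
      new <- nb[dist[nb] == Inf]
      dist[new] <- d
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  dist
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n)) {
    d <- bf_bfs_dist(adj, i)
    tot <- tot + sum(1 / d[-i][is.finite(d[-i])])
  }
  tot / (n * (n - 1))
}

bf_metrics <- function(adj) {
  n <- nrow(adj)
  dists <- t(vapply(seq_len(n), function(i) bf_bfs_dist(adj, i), numeric(n)))
  off <- dists[row(dists) != col(dists)]
  lp <- if (any(is.finite(off))) mean(off[is.finite(off)]) else 0
  cp <- mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    2 * sum(adj[nb, nb]) / 2 / (k * (k - 1))
  }, 0))
  el <- mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    bf_global_efficiency(adj[nb, nb, drop = FALSE])
  }, 0))
  list(E_glob = bf_global_efficiency(adj), E_loc = el, C_p = cp, L_p = lp)
}

# random simple graph on n nodes with edge probability p
random_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# adjusted Rand index (mclust is available in the test environment)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
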