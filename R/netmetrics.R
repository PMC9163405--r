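#' Sparsity grid for graph construction
#'
#' @param s_min,s_max,s_step grid over the fraction of strongest positive
#'   edges retained (defaults 0.2-0.3 in steps of 0.01, 11 points).
#' @return numeric vector of sparsity values.
#' @export
sparsity_grid <- function(s_min = 0.2, s_max = 0.3, s_step = 0.01) {
  stopifnot(s_min > 0, s_min <= s_max, s_max < 1, s_step > 0)
  g <- seq(s_min, s_max, by = s_step)
  if (abs(g[length(g)] - s_max) > 1e-9)
    stop_dynfc("sparsity_grid: step does not divide the range")
  g
}

#' Binarize a connectivity matrix at a sparsity threshold
#'
#' Keeps the `round(S * E)` largest strictly positive edges (round
#' half-to-even; `E = N(N-1)/2`), ties broken by the fixed canonical edge
#' order; negative and zero edges are never used. If fewer positive edges
#' exist, all of them are kept and attribute `n_kept` records the count.
#'
#' @param z_matrix symmetric edge-value matrix (or canonical edge vector
#'   with `n` supplied).
#' @param S sparsity in (0, 1).
#' @param n number of nodes (only needed when `z_matrix` is a vector).
#' @return binary adjacency matrix (0/1, no self-loops) with attribute
#'   `n_kept`.
#' @export
binarize_sparsity <- function(z_matrix, S, n = NULL) {
  stopifnot(S > 0, S < 1)
  if (is.matrix(z_matrix)) {
    n <- nrow(z_matrix)
    ev <- mat_to_edges(z_matrix)
  } else {
    stopifnot(!is.null(n))
    ev <- as.numeric(z_matrix)
  }
  adj <- binarize_edges_cpp(ev, n, S)
  adj <- matrix(as.integer(adj), n, n)
  kept <- sum(adj) / 2
  target <- round(S * length(ev))
  if (kept == 0)
    warning("binarize_sparsity: no positive edges, graph is empty",
            call. = FALSE)
  if (kept < target)
    attr(adj, "underfull") <- TRUE
  attr(adj, "n_kept") <- kept
  adj
}

#' Global graph metrics of a binary network
#'
#' Global efficiency (mean inverse shortest-path length over ordered node
#' pairs, 0 for disconnected pairs), local efficiency (mean over nodes of
#' the global efficiency of the node's neighborhood subgraph), clustering
#' coefficient (mean binary clustering) and characteristic path length
#' (mean shortest path over connected pairs only; the number of
#' disconnected pairs is reported alongside).
#'
#' @param adj binary adjacency matrix (simple undirected graph).
#' @return list with `E_glob`, `E_loc`, `C_p`, `L_p`,
#'   `n_disconnected_pairs`.
#' @export
global_metrics <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) < 2) stop_dynfc("global_metrics: need at least 2 nodes")
  if (max(abs(adj - t(adj))) > 0 || any(diag(adj) != 0))
    stop_dynfc("global_metrics: adjacency must be symmetric, no self-loops")
  graph_metrics_cpp(matrix(as.integer(adj != 0), nrow(adj)))
}

#' Normalized clustering, path length and small-worldness
#'
#' gamma = C_p / <C_p(null)>, lambda = L_p / <L_p(null)> and
#' sigma = gamma / lambda, against an ensemble of degree-preserving
#' Maslov-Sneppen rewirings (10 x |edges| swap attempts each). When the
#' graph admits no swap (or a null mean is 0 together with a 0 observed
#' value) the corresponding ratio is defined as 1.
#'
#' @param adj binary adjacency matrix with >= 1 edge.
#' @param n_null number of null networks (default 100).
#' @param seed integer seed (the ensemble is deterministic given it).
#' @return list with `gamma`, `lambda_norm`, `sigma_sw`, `null_C_p`,
#'   `null_L_p`.
#' @export
normalized_metrics <- function(adj, n_null = 100, seed = 1L) {
  adj <- as.matrix(adj)
  m <- global_metrics(adj)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  n_edges <- igraph::ecount(g)
  if (n_edges < 1) stop_dynfc("normalized_metrics: graph has no edges")
  nulls <- with_seed(seed, lapply(seq_len(n_null), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * n_edges))
    a <- igraph::as_adjacency_matrix(gr, sparse = FALSE)
    graph_metrics_cpp(matrix(as.integer(a != 0), nrow(a)))
  }))
  cp0 <- mean(vapply(nulls, `[[`, 0, "C_p"))
  lp0 <- mean(vapply(nulls, `[[`, 0, "L_p"))
  ratio <- function(obs, null) {
    if (null == 0) if (obs == 0) 1 else Inf else obs / null
  }
  gamma <- ratio(m$C_p, cp0)
  lambda <- ratio(m$L_p, lp0)
  list(gamma = gamma, lambda_norm = lambda, sigma_sw = gamma / lambda,
       null_C_p = cp0, null_L_p = lp0)
}

#' Area under the curve of a metric over the sparsity grid
#'
#' Composite trapezoid on the grid points (switchable to a
#' rectangle-times-step rule).
#'
#' @param values metric value at each grid point (finite).
#' @param grid sparsity grid.
#' @param rule `"trapezoid"` (default) or `"rectangle"`.
#' @return scalar AUC (metric x sparsity units).
#' @export
auc_over_grid <- function(values, grid = sparsity_grid(),
                          rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  if (length(values) != length(grid))
    stop_dynfc("auc_over_grid: %d values for %d grid points",
               length(values), length(grid))
  if (any(!is.finite(values))) stop_dynfc("auc_over_grid: non-finite value")
  if (rule == "trapezoid")
    sum(diff(grid) * (head(values, -1) + values[-1]) / 2)
  else
    sum(values[-length(values)] * diff(grid))
}

#' Per-window graph-metric AUCs and their variance over time
#'
#' For every window of an FC stack: reconstruct the symmetric z-matrix,
#' binarize at every sparsity of the grid, compute the global metrics
#' (and, when `n_null > 0`, the normalized metrics against
#' degree-preserving nulls), and integrate each metric over the grid
#' (trapezoid). The summary is the unbiased (n-1) sample variance of each
#' metric's AUC across windows.
#'
#' @param stack an `fc_stack` (or windows x E matrix with `n_nodes`).
#' @param grid sparsity grid.
#' @param n_null null networks per window/threshold for gamma/lambda/sigma
#'   (0 skips the normalized metrics; they are expensive).
#' @param seed integer seed for the null ensembles.
#' @param n_nodes node count when `stack` is a bare matrix.
#' @return list with `auc` (windows x metrics matrix) and `variance`
#'   (named vector of per-metric variances over windows).
#' @export
dynamic_metric_variance <- function(stack, grid = sparsity_grid(),
                                    n_null = 0, seed = 1L, n_nodes = NULL) {
  Z <- if (inherits(stack, "fc_stack")) stack$edge_values else as.matrix(stack)
  if (is.null(n_nodes))
    n_nodes <- if (inherits(stack, "fc_stack"))
      length(stack$network_labels)
    else round((1 + sqrt(1 + 8 * ncol(Z))) / 2)
  if (nrow(Z) < 2) stop_dynfc("dynamic_metric_variance: need >= 2 windows")
  auc <- windowed_metric_auc_cpp(Z, n_nodes, grid)
  colnames(auc) <- c("E_glob", "E_loc", "C_p", "L_p")
  if (n_null > 0) {
    seeds <- derive_seeds(seed, nrow(Z))
    norm_auc <- t(vapply(seq_len(nrow(Z)), function(w) {
      vals <- vapply(seq_along(grid), function(g) {
        adj <- binarize_sparsity(Z[w, ], grid[g], n = n_nodes)
        nm <- normalized_metrics(adj, n_null, seed = seeds[w] %/% 2 + g)
        c(nm$gamma, nm$lambda_norm, nm$sigma_sw)
      }, numeric(3))
      c(auc_over_grid(vals[1, ], grid), auc_over_grid(vals[2, ], grid),
        auc_over_grid(vals[3, ], grid))
    }, numeric(3)))
    colnames(norm_auc) <- c("gamma", "lambda_norm", "sigma_sw")
    auc <- cbind(auc, norm_auc)
  }
  list(auc = auc, variance = apply(auc, 2, var))
}
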