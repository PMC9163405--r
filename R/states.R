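#' K-means clustering of windowed FC with Manhattan distance
#'
#' Two-pass scheme: pass 1 runs L1 k-means (Manhattan-distance assignment,
#' element-wise-median centroid update) from `n_replicates` random
#' initializations and keeps the solution with the lowest total L1
#' objective; pass 2 re-clusters all windows from those centroids to
#' convergence. Assignment ties go to the lowest state index; empty
#' clusters are re-seeded from the window farthest from its centroid.
#' Final state labels are ordered by descending total occupancy.
#'
#' @param windows pooled windows x E matrix (all subjects).
#' @param k number of states.
#' @param n_replicates random initializations in pass 1 (default 100).
#' @param seed integer seed.
#' @param max_iter iteration cap per run.
#' @return object of class `state_model`: `k`, `centroids` (k x E),
#'   `assignments` (1..k per window), `objective`, `objective_trace`
#'   (pass-2 per-iteration objective), `replicate_seeds`.
#' @export
kmeans_l1 <- function(windows, k, n_replicates = 100, seed = 1L,
                      max_iter = 100) {
  windows <- as.matrix(windows)
  n <- nrow(windows)
  if (k > nrow(unique(windows)))
    stop_dynfc("kmeans_l1: k = %d exceeds number of distinct windows", k)
  rep_seeds <- derive_seeds(seed, n_replicates)
  best <- NULL
  for (r in seq_len(n_replicates)) {
    init <- with_seed(rep_seeds[r], windows[sample.int(n, k), , drop = FALSE])
    fit <- kmeans_l1_core(windows, init, max_iter, 1e-9)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  final <- kmeans_l1_core(windows, best$centroids, max_iter, 1e-9)
  labels <- final$labels + 1L
  # relabel by descending occupancy (ties by original index)
  occ <- tabulate(labels, k)
  ord <- order(-occ, seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(k = k,
                 centroids = final$centroids[ord, , drop = FALSE],
                 assignments = relabel[labels],
                 objective = final$objective,
                 objective_trace = final$objective_trace,
                 replicate_seeds = rep_seeds),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d, %d windows, objective %.4g\n",
              x$k, length(x$assignments), x$objective))
  invisible(x)
}

#' Choose the number of states by the elbow criterion
#'
#' Runs L1 k-means for every k in `k_range` and computes the ratio of
#' within-cluster to between-cluster Manhattan distance. The elbow is
#' located by a first-plateau rule: k is increased while the ratio still
#' improves by more than `rel_tol` of its current value, and the last k
#' that brought a real improvement is returned. A single-element range is
#' returned as-is. Large pooled matrices are subsampled to `max_windows`
#' rows (deterministically per seed); sharper results come from passing
#' [exemplar_windows()] rather than the full transition-diluted pool.
#'
#' @param windows pooled windows x E matrix.
#' @param k_range candidate k values (default 2:10).
#' @param seed integer seed.
#' @param n_replicates k-means replicates per candidate k.
#' @param max_windows subsample cap.
#' @param rel_tol minimum relative improvement that counts as progress.
#' @return the selected k.
#' @export
elbow_select_k <- function(windows, k_range = 2:10, seed = 1L,
                           n_replicates = 5, max_windows = 5000,
                           rel_tol = 0.005) {
  windows <- as.matrix(windows)
  if (nrow(unique(windows)) < 2)
    stop_dynfc("elbow_select_k: degenerate pooled data (all windows equal)")
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 1) return(k_range)
  if (any(k_range < 2) || any(k_range > nrow(windows) - 1))
    stop_dynfc("elbow_select_k: k_range must lie in [2, n_windows - 1]")
  if (nrow(windows) > max_windows)
    windows <- with_seed(seed,
      windows[sample.int(nrow(windows), max_windows), , drop = FALSE])
  ratio <- vapply(seq_along(k_range), function(i) {
    sm <- kmeans_l1(windows, k_range[i], n_replicates,
                    seed = seed + i, max_iter = 50)
    D <- l1_dist_cpp(windows, sm$centroids)
    idx <- cbind(seq_len(nrow(windows)), sm$assignments)
    within <- mean(D[idx])
    between <- mean(D[-(idx[, 1] + (idx[, 2] - 1) * nrow(D))])
    within / between
  }, 0)
  # first-plateau rule: walk up the k grid while the ratio still improves
  # by more than a small fraction of its current value; the elbow is the
  # last k that still brought a real improvement. In noisy, overlapping
  # window data the ratio levels off (or rises) right after the true k,
  # while the absolute drops before it can be arbitrarily uneven.
  k_sel <- k_range[1]
  for (i in seq_len(length(k_range) - 1)) {
    if (ratio[i] - ratio[i + 1] < rel_tol * ratio[i]) break
    k_sel <- k_range[i + 1]
  }
  k_sel
}

#' Exemplar windows of an FC stack
#'
#' Windows at local maxima (in time) of the L1 deviation from the
#' subject's mean connectivity pattern. Exemplars tend to fall mid-dwell,
#' away from state boundaries, and are the conventional input for
#' choosing the number of states: clusters are much sharper on exemplars
#' than on the full, transition-diluted window pool.
#'
#' @param stack an `fc_stack` (or windows x E matrix).
#' @return integer indices of the exemplar windows.
#' @export
exemplar_windows <- function(stack) {
  Z <- if (inherits(stack, "fc_stack")) stack$edge_values else
    as.matrix(stack)
  dev <- rowSums(abs(sweep(Z, 2, colMeans(Z))))
  n <- length(dev)
  if (n <= 2) return(seq_len(n))
  which(dev >= c(dev[1], head(dev, -1)) & dev >= c(dev[-1], dev[n]))
}

#' Temporal metrics of a state-assignment sequence
#'
#' Fractional windows (occupancy), mean dwell time (mean length of maximal
#' consecutive runs, in windows; 0 for unvisited states) and the number of
#' transitions (adjacent label changes).
#'
#' @param assignments integer labels in 1..k for one subject's windows.
#' @param k number of states.
#' @return object of class `temporal_metrics`: list with
#'   `fractional_windows`, `mean_dwell`, `n_transitions`, `n_runs`.
#' @export
temporal_metrics <- function(assignments, k) {
  a <- as.integer(assignments)
  if (!length(a)) stop_dynfc("temporal_metrics: empty sequence")
  if (any(a < 1 | a > k)) stop_dynfc("temporal_metrics: label out of 1..%d", k)
  r <- rle(a)
  n_runs <- vapply(seq_len(k), function(s) sum(r$values == s), 0L)
  dwell <- vapply(seq_len(k), function(s) {
    if (n_runs[s] == 0) 0 else mean(r$lengths[r$values == s])
  }, 0)
  structure(list(
    fractional_windows = tabulate(a, k) / length(a),
    mean_dwell = dwell,
    n_transitions = length(r$values) - 1L,
    n_runs = n_runs), class = "temporal_metrics")
}

#' Subject- and group-level state centroids
#'
#' The subject centroid of a state is the element-wise median over that
#' subject's windows assigned to the state (missing if the subject never
#' visits it); the group centroid is the element-wise mean over subjects
#' with non-missing centroids.
#'
#' @param stack an `fc_stack` (or a windows x E matrix).
#' @param assignments state labels for the subject's windows.
#' @param k number of states.
#' @return k x E matrix of medians; rows of unvisited states are `NA`.
#' @export
subject_state_centroid <- function(stack, assignments, k) {
  Z <- if (inherits(stack, "fc_stack")) stack$edge_values else as.matrix(stack)
  stopifnot(nrow(Z) == length(assignments))
  out <- matrix(NA_real_, k, ncol(Z))
  colnames(out) <- colnames(Z)
  for (s in seq_len(k)) {
    idx <- which(assignments == s)
    if (length(idx) == 1) out[s, ] <- Z[idx, ]
    else if (length(idx) > 1) out[s, ] <- apply(Z[idx, , drop = FALSE], 2,
                                                median)
  }
  out
}

#' @rdname subject_state_centroid
#' @param subject_centroids list of k x E subject centroid matrices.
#' @return `group_state_centroid()`: k x E matrix of means over subjects
#'   with non-missing state centroids.
#' @export
group_state_centroid <- function(subject_centroids) {
  k <- nrow(subject_centroids[[1]])
  E <- ncol(subject_centroids[[1]])
  out <- matrix(NA_real_, k, E, dimnames =
                  list(NULL, colnames(subject_centroids[[1]])))
  for (s in seq_len(k)) {
    rows <- do.call(rbind, lapply(subject_centroids, function(m) m[s, ]))
    ok <- rowSums(is.na(rows)) == 0
    if (any(ok)) out[s, ] <- colMeans(rows[ok, , drop = FALSE])
  }
  out
}

#' Match states between two centroid sets by highest correlation
#'
#' Computes Pearson correlations between all centroid pairs and matches
#' greedily by descending correlation (each row/column used once). Used to
#' identify "the same state" across analyses with different window
#' lengths. Warns if the greedy match is not a bijection over the smaller
#' set.
#'
#' @param centroids_a,centroids_b k x E centroid matrices (equal E).
#' @return list with `permutation` (for each row of `a`, the matched row
#'   of `b`, `NA` if unmatched), `correlations` (k_a x k_b matrix) and
#'   `matched_correlations`.
#' @export
match_states <- function(centroids_a, centroids_b) {
  if (ncol(centroids_a) != ncol(centroids_b))
    stop_dynfc("match_states: edge dimensions differ")
  if (any(apply(centroids_a, 1, sd) == 0) ||
      any(apply(centroids_b, 1, sd) == 0))
    stop_dynfc("match_states: zero-variance centroid")
  R <- cor(t(centroids_a), t(centroids_b))
  ka <- nrow(R); kb <- ncol(R)
  perm <- rep(NA_integer_, ka)
  used_b <- logical(kb)
  Rw <- R
  for (step in seq_len(min(ka, kb))) {
    pos <- which(Rw == max(Rw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    perm[pos[1]] <- pos[2]
    used_b[pos[2]] <- TRUE
    Rw[pos[1], ] <- NA
    Rw[, pos[2]] <- NA
  }
  # greedy is not a bijection if some row's best match was taken
  best <- apply(R, 1, which.max)
  if (any(!is.na(perm) & best != perm))
    warning("match_states: greedy matching is not the row-wise argmax ",
            "for every state", call. = FALSE)
  list(permutation = perm, correlations = R,
       matched_correlations = R[cbind(seq_len(ka), perm)])
}

#' Strongest-connection mask of a state centroid
#'
#' Keeps the `ceiling(fraction * E)` edges with the largest absolute
#' value, preserving their sign; ties are broken by the fixed canonical
#' edge order.
#'
#' @param values edge vector (or symmetric matrix) of one state.
#' @param fraction fraction of edges to keep (default 0.05).
#' @return integer vector in -1/0/+1 per edge (sign of kept edges).
#' @export
top_fraction_edges <- function(values, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.matrix(values) && nrow(values) == ncol(values))
    values <- mat_to_edges(values)
  E <- length(values)
  m <- ceiling(fraction * E)
  ord <- order(-abs(values), seq_len(E))
  mask <- integer(E)
  keep <- ord[seq_len(m)]
  mask[keep] <- ifelse(values[keep] >= 0, 1L, -1L)
  mask
}
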