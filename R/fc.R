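#' Static functional connectivity over the full scan
#'
#' Pairwise Pearson correlations between all network signals, converted to
#' z-values by the Fisher r-to-z transform (`atanh`), with r clipped to
#' `+-(1 - 1e-7)` so z stays finite. The diagonal is set to 0 by
#' convention.
#'
#' @param tc a [timecourse()].
#' @return symmetric z-matrix with network labels.
#' @export
static_fc <- function(tc) {
  X <- tc$data
  if (nrow(X) < 3) stop_dynfc("static_fc: need at least 3 timepoints")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop_dynfc("static_fc: constant network signal (%s)",
               paste(tc$network_labels[sds == 0], collapse = ", "))
  z <- fisher_z(cor(X))
  diag(z) <- 0
  dimnames(z) <- list(tc$network_labels, tc$network_labels)
  z
}

#' Taper-weighted covariance of one window
#'
#' Removes the weighted mean and returns
#' `Sigma = sum_t w_t (x_t - mu)(x_t - mu)^T` for the window rows selected
#' by `start`. With uniform weights this is the 1/W-normalized sample
#' covariance.
#'
#' @param tc a [timecourse()].
#' @param weights nonnegative taper weights summing to 1.
#' @param start first timepoint of the window.
#' @return symmetric positive semi-definite covariance matrix.
#' @export
weighted_window_covariance <- function(tc, weights, start = 1L) {
  W <- length(weights)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop_dynfc("weights must be nonnegative and sum to 1")
  if (sum(weights > 0) < 2)
    stop_dynfc("degenerate window: all weight on one timepoint")
  X <- tc$data[start:(start + W - 1L), , drop = FALSE]
  mu <- colSums(X * weights)
  Xc <- sweep(X, 2, mu)
  crossprod(Xc * sqrt(weights))
}

#' Graphical-LASSO configuration
#'
#' @param penalty_grid candidate L1 penalties (sorted, deduplicated).
#' @param n_repeats cross-validation repeats for penalty selection
#'   (default 50).
#' @param cv_fraction fraction of windows held out per repeat.
#' @param max_iter,tol solver controls.
#' @return object of class `glasso_config`.
#' @export
glasso_config <- function(penalty_grid = c(0.01, 0.02, 0.05, 0.1, 0.2),
                          n_repeats = 50, cv_fraction = 0.2,
                          max_iter = 200, tol = 1e-4) {
  penalty_grid <- sort(unique(penalty_grid))
  if (!length(penalty_grid) || any(penalty_grid < 0))
    stop_dynfc("penalty grid must be nonempty and nonnegative")
  stopifnot(cv_fraction > 0, cv_fraction < 1, n_repeats >= 1)
  structure(list(penalty_grid = penalty_grid, n_repeats = n_repeats,
                 cv_fraction = cv_fraction, max_iter = max_iter, tol = tol),
            class = "glasso_config")
}

#' Graphical LASSO: L1-penalized sparse inverse covariance
#'
#' Maximizes `log det(Theta) - tr(S Theta) - rho * ||Theta||_1(offdiag)`
#' by block coordinate descent. At `rho = 0` the precision is the plain
#' matrix inverse.
#'
#' @param S symmetric covariance matrix with positive diagonal.
#' @param rho L1 penalty, >= 0.
#' @param max_iter,tol solver controls.
#' @return list with `w` (regularized covariance), `theta` (precision),
#'   `gap` (duality gap) and `iterations`.
#' @export
graphical_lasso <- function(S, rho, max_iter = 200, tol = 1e-4) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-8) stop_dynfc("graphical_lasso: S not symmetric")
  if (any(diag(S) <= 0)) stop_dynfc("graphical_lasso: nonpositive diagonal")
  if (rho < 0) stop_dynfc("graphical_lasso: rho must be >= 0")
  fit <- glasso_cpp((S + t(S)) / 2, rho, max_iter, tol)
  if (!fit$converged)
    stop_dynfc("graphical_lasso did not converge in %d iterations (gap %.3g)",
               max_iter, fit$gap)
  fit
}

#' Select the graphical-LASSO penalty by repeated cross-validation
#'
#' For each of `n_repeats` random splits of the windows, fits the
#' graphical LASSO on the mean covariance of the training windows at every
#' grid penalty and scores the Gaussian log-likelihood
#' `log det(Theta) - tr(S_test Theta)` on the mean held-out covariance.
#' Returns the penalty with the highest mean held-out score.
#'
#' @param covs list of window covariance matrices for one subject.
#' @param gcfg a [glasso_config()].
#' @param seed integer seed (splits are deterministic given the seed).
#' @return the selected penalty (scalar).
#' @export
select_penalty <- function(covs, gcfg = glasso_config(), seed = 1L) {
  if (length(covs) < 2) stop_dynfc("select_penalty: need >= 2 windows")
  grid <- gcfg$penalty_grid
  if (length(grid) == 1) return(grid)
  n <- length(covs)
  n_test <- max(1L, floor(gcfg$cv_fraction * n))
  scores <- matrix(NA_real_, gcfg$n_repeats, length(grid))
  with_seed(seed, {
    for (r in seq_len(gcfg$n_repeats)) {
      test <- sample.int(n, n_test)
      S_train <- Reduce(`+`, covs[-test]) / (n - n_test)
      S_test <- Reduce(`+`, covs[test]) / n_test
      for (g in seq_along(grid)) {
        fit <- try(glasso_cpp(S_train, grid[g], gcfg$max_iter, gcfg$tol),
                   silent = TRUE)
        if (inherits(fit, "try-error")) next
        det_t <- determinant(fit$theta, logarithm = TRUE)
        if (det_t$sign <= 0) next
        scores[r, g] <- as.numeric(det_t$modulus) -
          sum(S_test * fit$theta)
      }
    }
  })
  mean_scores <- colMeans(scores, na.rm = TRUE)
  grid[which.max(mean_scores)]
}

#' Windowed dynamic FC for one subject
#'
#' For every tapered window: weighted covariance, graphical-LASSO
#' regularization at the subject-level penalty (selected by
#' [select_penalty()] unless the grid has a single value), correlation
#' from the regularized covariance, Fisher r-to-z, and vectorization to
#' the canonical upper-triangle edge order.
#'
#' @param tc a (preprocessed) [timecourse()].
#' @param wspec a [tapered_window_spec()].
#' @param gcfg a [glasso_config()]; use `glasso_config(penalty_grid = 0)`
#'   to disable regularization.
#' @param seed seed for penalty selection.
#' @return object of class `fc_stack`: list with `subject_id`,
#'   `edge_values` (windows x E z-matrix), `edge_index`, `window_centers`,
#'   `n_windows`, `penalty`, `network_labels`.
#' @export
dynamic_fc <- function(tc, wspec = tapered_window_spec(),
                       gcfg = glasso_config(), seed = 1L) {
  win <- make_tapered_windows(nrow(tc$data), wspec)
  covs <- lapply(win$starts, function(st)
    weighted_window_covariance(tc, win$weights, st))
  rho <- if (length(gcfg$penalty_grid) == 1) gcfg$penalty_grid
         else select_penalty(covs, gcfg, seed)
  n <- ncol(tc$data)
  E <- n * (n - 1) / 2
  Z <- matrix(NA_real_, win$n_windows, E)
  for (w in seq_len(win$n_windows)) {
    Wreg <- if (rho > 0)
      glasso_cpp(covs[[w]], rho, gcfg$max_iter, gcfg$tol)$w
    else covs[[w]]
    r <- stats::cov2cor(Wreg)
    Z[w, ] <- fisher_z(mat_to_edges(r))
  }
  ei <- edge_index(n)
  colnames(Z) <- paste(tc$network_labels[ei[, 1]],
                       tc$network_labels[ei[, 2]], sep = "_")
  structure(list(subject_id = tc$subject_id, edge_values = Z,
                 edge_index = ei, window_centers = win$centers,
                 n_windows = win$n_windows, penalty = rho,
                 network_labels = tc$network_labels),
            class = "fc_stack")
}

#' @export
print.fc_stack <- function(x, ...) {
  cat(sprintf("<fc_stack> %s: %d windows x %d edges (penalty %g)\n",
              x$subject_id, x$n_windows, ncol(x$edge_values), x$penalty))
  invisible(x)
}

#' Residualize windowed FC on subject-level covariates
#'
#' For every (window, edge) cell, fits an across-subject linear model on
#' the z-scored covariates and returns the residual plus the grand
#' intercept, so group analyses are free of age / sex / education / motion
#' effects.
#'
#' @param stacks list of `fc_stack` objects, one per subject, all with the
#'   same window/edge geometry (subject order defines the rows).
#' @param covariates data frame with one row per subject.
#' @param columns covariate columns to regress out.
#' @return list of `fc_stack` objects with residualized `edge_values`.
#' @export
residualize_covariates <- function(stacks, covariates,
                                   columns = c("age", "sex", "education",
                                               "mean_fd")) {
  n_sub <- length(stacks)
  if (nrow(covariates) != n_sub)
    stop_dynfc("covariate table has %d rows for %d subjects",
               nrow(covariates), n_sub)
  missing_cols <- setdiff(columns, names(covariates))
  if (length(missing_cols))
    stop_dynfc("missing covariates: %s", paste(missing_cols, collapse = ", "))
  C <- as.matrix(covariates[, columns, drop = FALSE])
  if (any(!is.finite(C)))
    stop_dynfc("non-finite values in covariates %s",
               paste(columns, collapse = ", "))
  C <- scale(C)
  C[is.nan(C)] <- 0  # constant covariate -> no effect beyond intercept
  C <- C[, colSums(abs(C)) > 0, drop = FALSE]
  X <- cbind(1, C)
  q <- qr(X)
  if (q$rank < ncol(X)) stop_dynfc("rank-deficient covariate design")
  dims <- dim(stacks[[1]]$edge_values)
  Y <- t(vapply(stacks, function(s) as.numeric(s$edge_values),
                numeric(prod(dims))))
  res <- qr.resid(q, Y)
  grand <- colMeans(Y)
  res <- sweep(res, 2, grand, `+`)
  for (i in seq_len(n_sub)) {
    stacks[[i]]$edge_values <- matrix(res[i, ], dims[1], dims[2],
                                      dimnames =
                                        dimnames(stacks[[i]]$edge_values))
  }
  stacks
}
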