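#' Simulate one subject's network time courses
#'
#' Samples a hidden Markov chain over connectivity states (one step per
#' timepoint) from the group's transition matrix, draws each observation
#' from the active state's covariance, applies AR(1) smoothing
#' (`y_t = phi * y_{t-1} + sqrt(1 - phi^2) * e_t`, which preserves the
#' marginal covariance) and adds isotropic observation noise. Any
#' edge-weakening effects configured for the group are applied to the state
#' covariances (with SPD repair) before sampling.
#'
#' @param spec a [synth_spec()].
#' @param group group label, must index `spec$transition_matrix_per_group`.
#' @param seed integer seed; identical `(spec, group, seed)` gives
#'   bit-identical output.
#' @param subject_id subject identifier for the returned [timecourse()].
#' @return list with `tc` (a [timecourse()]) and `truth` (a list with the
#'   per-timepoint `state_sequence`, the group-adjusted
#'   `state_covariances`, `n_switches` and per-state `occupancy`).
#' @export
simulate_subject <- function(spec, group, seed, subject_id = "subj") {
  P <- spec$transition_matrix_per_group[[group]]
  if (is.null(P)) stop_dynfc("unknown group '%s'", group)
  if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-12)
    stop_dynfc("transition matrix for group '%s' is not row-stochastic", group)
  covs <- group_state_covariances(spec, group)
  chol_l <- lapply(covs, function(C) t(chol(C)))
  n <- spec$n_networks
  T_ <- spec$n_timepoints
  phi <- spec$ar_coeff

  sim <- with_seed(seed, {
    s <- integer(T_)
    s[1] <- sample.int(spec$k_states, 1, prob = spec$initial_distribution)
    for (t in 2:T_) s[t] <- sample.int(spec$k_states, 1, prob = P[s[t - 1], ])
    E <- matrix(rnorm(T_ * n), T_, n)
    X <- matrix(0, T_, n)
    innov_scale <- sqrt(1 - phi^2)
    prev <- as.numeric(chol_l[[s[1]]] %*% E[1, ])
    X[1, ] <- prev
    if (T_ > 1) for (t in 2:T_) {
      e <- as.numeric(chol_l[[s[t]]] %*% E[t, ])
      prev <- phi * prev + innov_scale * e
      X[t, ] <- prev
    }
    if (spec$noise_sd > 0)
      X <- X + matrix(rnorm(T_ * n, sd = spec$noise_sd), T_, n)
    list(s = s, X = X)
  })

  tc <- timecourse(sim$X, rsn_labels()[seq_len(n)], tr = spec$tr,
                   subject_id = subject_id)
  truth <- list(
    state_sequence = sim$s,
    state_covariances = covs,
    n_switches = sum(diff(sim$s) != 0),
    occupancy = tabulate(sim$s, spec$k_states) / T_,
    group = group
  )
  list(tc = tc, truth = truth)
}

# State covariances after applying the group's edge-weakening effects.
group_state_covariances <- function(spec, group) {
  covs <- spec$state_covariances
  for (ef in spec$edge_effects) {
    if (ef$group != group || ef$factor == 1) next
    C <- covs[[ef$state]]
    for (r in seq_len(nrow(ef$edges))) {
      i <- ef$edges$i[r]; j <- ef$edges$j[r]
      C[i, j] <- C[i, j] * ef$factor
      C[j, i] <- C[i, j]
    }
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < 1e-6)
      C <- spd_repair(C, state = ef$state)
    covs[[ef$state]] <- C
  }
  covs
}

#' Default linear models linking cognition to the true dynamics
#'
#' Each score is `intercept + b_trans * n_switches + b_occ3 * occupancy_3 +
#' Normal(0, sd)`. Coefficients are anchored so that the group means of the
#' default cohort land near typical clinical values (TMT completion times
#' rising, MMSE/MoCA/SDMT falling, as switching drops and State-3
#' occupancy grows).
#' @export
cognition_config <- function() {
  list(
    TMT_A = list(intercept = 77.2,  b_trans = -4.0, b_occ3 = 27,  sd = 10),
    TMT_B = list(intercept = 121.5, b_trans = -6.0, b_occ3 = 34,  sd = 12),
    MMSE  = list(intercept = 26.41, b_trans = 0.35, b_occ3 = -2.6, sd = 1.5),
    MoCA  = list(intercept = 25.00, b_trans = 0.40, b_occ3 = -2.2, sd = 1.8),
    SDMT  = list(intercept = 42.66, b_trans = 1.10, b_occ3 = -6.0, sd = 8)
  )
}

#' Simulate a full cohort with covariates and ground truth
#'
#' Subject seeds are derived deterministically from the master seed.
#' Demographics are drawn per group (age ~ 36 +- 9.5 years, balanced sex,
#' education ~ 11.5 +- 3 years, mean framewise displacement ~ 0.05 mm,
#' disease duration for patient groups only) and cognitive scores follow
#' the configured linear dependence on each subject's true number of state
#' switches and State-3 occupancy, so downstream correlation analyses have
#' a recoverable signal.
#'
#' @param spec a [synth_spec()].
#' @param n_per_group named counts, e.g. `c(HD = 50, NonD = 50, HC = 64)`.
#' @param seed master seed.
#' @param cognition list of score models, see [cognition_config()].
#' @return list with `timecourses` (list of [timecourse()]), `covariates`
#'   (data frame, one row per subject) and `truth` (list of ground-truth
#'   lists).
#' @export
simulate_cohort <- function(spec,
                            n_per_group = c(HD = 50, NonD = 50, HC = 64),
                            seed = spec$seed,
                            cognition = cognition_config()) {
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups)))
    stop_dynfc("n_per_group must be a named vector of group counts")
  n_per_group <- n_per_group[n_per_group > 0]
  if (!length(n_per_group)) stop_dynfc("empty cohort")
  group_of <- rep(names(n_per_group), n_per_group)
  n_sub <- length(group_of)
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  seeds <- derive_seeds(seed, n_sub + 1L)
  subj_seeds <- seeds[seq_len(n_sub)]

  tcs <- vector("list", n_sub)
  truths <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sim <- simulate_subject(spec, group_of[i], subj_seeds[i], ids[i])
    tcs[[i]] <- sim$tc
    truths[[i]] <- sim$truth
  }
  names(tcs) <- ids

  cov_tab <- with_seed(seeds[n_sub + 1L], {
    age_mean <- c(HD = 36.1, NonD = 35.6, HC = 34.6)[group_of]
    age_mean[is.na(age_mean)] <- 36
    df <- data.frame(
      subject_id = ids,
      group = group_of,
      age = round(pmax(18, rnorm(n_sub, age_mean, 9.5)), 1),
      sex = rbinom(n_sub, 1, 0.53),
      education = round(pmin(20, pmax(3, rnorm(n_sub, 11.5, 3))), 1),
      mean_fd = round(pmin(0.2, abs(rnorm(n_sub, 0.05, 0.03)) + 0.005), 4),
      disease_duration = ifelse(group_of == "HC", NA,
                                round(exp(rnorm(n_sub, log(40), 0.6)), 1)),
      stringsAsFactors = FALSE
    )
    for (score in names(cognition)) {
      m <- cognition[[score]]
      occ3 <- vapply(truths, function(tr)
        if (length(tr$occupancy) >= 3) tr$occupancy[3] else 0, 0)
      mu <- m$intercept +
        m$b_trans * vapply(truths, function(tr) tr$n_switches, 0) +
        m$b_occ3 * occ3
      df[[score]] <- round(mu + rnorm(n_sub, sd = m$sd), 1)
    }
    df
  })

  list(timecourses = tcs, covariates = cov_tab, truth = truths)
}

#' Map per-timepoint ground-truth states onto the window grid
#'
#' Windows inherit the majority state label of the timepoints they cover;
#' ties are broken toward the lowest state index. The windowed labels are
#' then summarized with [temporal_metrics()], giving the oracle against
#' which recovered temporal metrics are scored.
#'
#' @param truth ground-truth list from [simulate_subject()] (or any list
#'   with a `state_sequence` element).
#' @param wspec a [tapered_window_spec()].
#' @param k_states number of states (defaults to max observed label).
#' @return list with `window_labels` and `metrics` (a [temporal_metrics()]
#'   result).
#' @export
ground_truth_temporal_metrics <- function(truth, wspec = tapered_window_spec(),
                                          k_states = max(truth$state_sequence)) {
  s <- truth$state_sequence
  win <- make_tapered_windows(length(s), wspec)
  labels <- vapply(win$starts, function(st) {
    cnt <- tabulate(s[st:(st + wspec$window_length_tr - 1L)], k_states)
    which.max(cnt)  # ties -> lowest state index
  }, 0L)
  list(window_labels = labels,
       metrics = temporal_metrics(labels, k_states))
}
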