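#' Resting-state network labels of the 14-network parcellation
#'
#' Dorsal/ventral default mode and precuneus networks, auditory, dorsal
#' attention, primary/higher visual, sensorimotor, anterior/posterior
#' salience, right/left executive control, language and basal ganglia
#' networks.
#' @export
rsn_labels <- function() {
  c("dDMN", "vDMN", "PRE", "AN", "DAN", "pVN", "hVN",
    "SMN", "aSN", "pSN", "RECN", "LECN", "LAN", "BG")
}

#' Default per-state block designs for the simulator
#'
#' Each state is a list of signed network-pair strengths defining its
#' correlation structure. The four defaults realize the
#' segregation/integration contrast that recurring connectivity states
#' show in 14-network resting-state data, so that the states differ both
#' in edge space (for clustering) and in binarized-graph topology (so
#' that switching between states moves the efficiency metrics):
#'
#' * State 1 — modular: strong positive cliques within DMN,
#'   visual/sensorimotor, executive-control and salience blocks (high
#'   clustering and local efficiency, longer between-module paths).
#' * State 2 — hub-integrated: positive spokes around dorsal-attention
#'   and posterior-salience hubs (short paths, low clustering).
#' * State 3 — DMN-dominant: a strong within-DMN clique with
#'   dDMN-language coupling and posterior-salience anticorrelation, plus
#'   a weak ring over the remaining networks. (The within-DMN pairs are
#'   the ones weakened by the patient edge effects.)
#' * State 4 — weakly connected: few strong positive pairs and broad
#'   posterior-salience anticorrelations.
#'
#' @param n_networks number of networks (default 14).
#' @param k_states number of states (default 4).
#' @return a list of `k_states` data frames with columns `i`, `j`, `value`.
#' @export
default_block_design <- function(n_networks = 14, k_states = 4) {
  lab <- rsn_labels()[seq_len(n_networks)]
  pair <- function(a, b, v) {
    ia <- match(a, lab); ib <- match(b, lab)
    data.frame(i = min(ia, ib), j = max(ia, ib), value = v)
  }
  clique <- function(members, v) {
    pr <- utils::combn(match(members, lab), 2)
    data.frame(i = pmin(pr[1, ], pr[2, ]), j = pmax(pr[1, ], pr[2, ]),
               value = v)
  }
  star <- function(hub, spokes, v) {
    ih <- match(hub, lab); is <- match(spokes, lab)
    data.frame(i = pmin(ih, is), j = pmax(ih, is), value = v)
  }
  named <- list(
    # State 1: modular / segregated (26 positive pairs in 3 modules, so
    # the thresholded graphs stay modular over the whole sparsity grid)
    rbind(clique(c("dDMN", "vDMN", "PRE", "LAN"), 0.60),
          clique(c("AN", "DAN", "pVN", "hVN", "SMN"), 0.55),
          clique(c("aSN", "pSN", "RECN", "LECN", "BG"), 0.50),
          pair("PRE", "pSN", -0.40), pair("vDMN", "pSN", -0.30)),
    # State 2: hub-integrated (12 cross-module spokes, triangle-free)
    rbind(star("DAN", c("dDMN", "AN", "aSN", "RECN", "LECN", "BG"), 0.42),
          star("pSN", c("vDMN", "PRE", "pVN", "hVN", "SMN", "LAN"), 0.42),
          pair("dDMN", "pSN", -0.30), pair("DAN", "LAN", -0.30)),
    # State 3: DMN-dominant and saturated (21 positive pairs: a tight DMN
    # core plus a strong ring-with-chords over the remaining networks, so
    # its thresholded edge set is stable; posterior salience
    # anticorrelated with the DMN)
    rbind(clique(c("dDMN", "vDMN", "PRE"), 0.70),
          data.frame(i = c(4, 7, 7, 6, 6, 8, 8, 11, 4),
                     j = c(7, 9, 13, 9, 12, 12, 11, 14, 14),
                     value = 0.55),
          data.frame(i = c(4, 12, 8, 12, 9), j = c(6, 13, 9, 14, 11),
                     value = 0.50),
          pair("DAN", "pSN", 0.60), pair("DAN", "PRE", 0.50),
          pair("dDMN", "LAN", 0.55),
          pair("dDMN", "pSN", -0.60), pair("PRE", "pSN", -0.60),
          pair("vDMN", "pSN", -0.40)),
    # State 4: weakly connected (6 positive pairs, noise-dominated graphs)
    rbind(pair("PRE", "pVN", 0.60), pair("dDMN", "BG", 0.50),
          pair("aSN", "LECN", 0.50), pair("hVN", "BG", 0.45),
          pair("vDMN", "DAN", 0.45), pair("AN", "SMN", 0.45),
          pair("pSN", "PRE", -0.55), pair("pSN", "SMN", -0.55),
          pair("pSN", "pVN", -0.55), pair("DAN", "aSN", -0.30))
  )
  out <- lapply(seq_len(k_states), function(s) {
    df <- if (s <= length(named)) named[[s]] else
      data.frame(i = integer(), j = integer(), value = numeric())
    df <- df[df$i <= n_networks & df$j <= n_networks, ]
    rownames(df) <- NULL
    df
  })
  out
}

#' Default per-group Markov transition matrices
#'
#' Hidden states switch per timepoint. Rows are "from" states; the
#' probability of leaving state s is a per-group, per-state leave rate, and
#' the destination is drawn proportionally to the base occupancy weights.
#' Defaults encode the study-condition gradient: healthy controls switch
#' most, hemodialysis patients least, and patients dwell longer in State 3.
#'
#' @param k_states number of states.
#' @param weights base occupancy weights (default c(0.27, 0.20, 0.34, 0.19)).
#' @return named list of row-stochastic k x k matrices for groups
#'   `HD`, `NonD`, `HC`.
#' @export
default_transition_matrices <- function(k_states = 4,
                                        weights = c(0.27, 0.20, 0.34, 0.19)) {
  stopifnot(k_states == length(weights))
  # per-state leave rates calibrated jointly so that (a) windowed-majority
  # transition counts fall across the HC > non-dialysis > HD gradient with
  # wide relative gaps, (b) State-3 occupancy rises across the same
  # gradient, and (c) scans stay smooth enough that windowed states remain
  # recoverable (window-overlap smearing grows with the switch rate)
  leave <- list(
    HC   = c(0.050, 0.050, 0.048, 0.054),
    NonD = c(0.052, 0.038, 0.0175, 0.050),
    HD   = c(0.058, 0.031, 0.0085, 0.050)
  )
  lapply(leave, function(lv) {
    P <- matrix(0, k_states, k_states)
    for (i in seq_len(k_states)) {
      w <- weights; w[i] <- 0
      P[i, ] <- lv[i] * w / sum(w)
      P[i, i] <- 1 - lv[i]
    }
    P
  })[c("HD", "NonD", "HC")]
}

#' Default DMN-block edge-weakening effects
#'
#' In State 3 the within-DMN pairs (dDMN-vDMN, dDMN-PRE, vDMN-PRE) are
#' multiplicatively weakened for the patient groups (factor 0.8 for
#' non-dialysis, 0.6 for hemodialysis), giving the simulated cohort a
#' recoverable state-specific connectivity deficit.
#' @return list of effects, each with `group`, `state`, `edges` (i/j data
#'   frame) and `factor`.
#' @export
default_edge_effects <- function() {
  lab <- rsn_labels()
  dmn <- c("dDMN", "vDMN", "PRE")
  ii <- match(dmn, lab)
  pairs <- t(utils::combn(ii, 2))
  edges <- data.frame(i = pmin(pairs[, 1], pairs[, 2]),
                      j = pmax(pairs[, 1], pairs[, 2]))
  list(
    list(group = "NonD", state = 3, edges = edges, factor = 0.8),
    list(group = "HD",   state = 3, edges = edges, factor = 0.6)
  )
}

#' Specification of the synthetic cohort generator
#'
#' Defines the hidden-Markov covariance-switching model: `k_states` SPD
#' correlation matrices over `n_networks` signals, per-group transition
#' matrices over states (one step per timepoint), AR(1) observation
#' smoothing and isotropic observation noise. Defaults reproduce the study
#' conditions: 14 networks, 170 timepoints at TR = 2 s, 4 states.
#'
#' @param n_networks,n_timepoints,tr,k_states scan geometry.
#' @param state_covariances list of SPD unit-diagonal matrices; built from
#'   `block_design` when `NULL`.
#' @param block_design per-state block designs (see
#'   [default_block_design()]).
#' @param transition_matrix_per_group named list of row-stochastic matrices.
#' @param initial_distribution probability vector over states.
#' @param edge_effects list of group/state edge-weakening effects.
#' @param noise_sd observation noise SD (a.u.).
#' @param ar_coeff lag-1 autocorrelation in `[0, 1)`.
#' @param seed default master seed.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_networks = 14, n_timepoints = 170, tr = 2,
                       k_states = 4,
                       state_covariances = NULL,
                       block_design = default_block_design(n_networks,
                                                           k_states),
                       transition_matrix_per_group =
                         default_transition_matrices(k_states),
                       initial_distribution = c(0.27, 0.20, 0.34, 0.19),
                       edge_effects = default_edge_effects(),
                       noise_sd = 0.2, ar_coeff = 0.3, seed = 1L) {
  spec <- structure(list(
    n_networks = n_networks, n_timepoints = n_timepoints, tr = tr,
    k_states = k_states, block_design = block_design,
    transition_matrix_per_group = transition_matrix_per_group,
    initial_distribution = initial_distribution,
    edge_effects = edge_effects, noise_sd = noise_sd,
    ar_coeff = ar_coeff, seed = seed), class = "synth_spec")
  if (is.null(state_covariances))
    state_covariances <- build_state_covariances(spec, block_design)
  spec$state_covariances <- state_covariances
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  with(spec, {
    stopifnot(n_networks >= 2, n_timepoints >= 2, tr > 0, k_states >= 1,
              noise_sd >= 0, ar_coeff >= 0, ar_coeff < 1)
    if (length(state_covariances) != k_states)
      stop_dynfc("need %d state covariances, got %d", k_states,
                 length(state_covariances))
    for (s in seq_along(state_covariances)) {
      C <- state_covariances[[s]]
      if (max(abs(C - t(C))) > 1e-10)
        stop_dynfc("state %d covariance not symmetric", s)
      if (max(abs(diag(C) - 1)) > 1e-8)
        stop_dynfc("state %d covariance diagonal not 1", s)
      if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0)
        stop_dynfc("state %d covariance not positive definite", s)
    }
    for (g in names(transition_matrix_per_group)) {
      P <- transition_matrix_per_group[[g]]
      if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-12)
        stop_dynfc("transition matrix for group %s is not row-stochastic", g)
    }
    if (abs(sum(initial_distribution) - 1) > 1e-12 ||
        any(initial_distribution < 0))
      stop_dynfc("initial distribution must be a probability vector")
    for (ef in edge_effects)
      if (ef$factor <= 0 || ef$factor > 1)
        stop_dynfc("edge-effect factors must lie in (0, 1]")
  })
  invisible(spec)
}

# Nearest-SPD repair: clip eigenvalues (at a floor comfortably above
# min_eig, so rescaling to unit diagonal cannot push them back under),
# rescale to unit diagonal, iterate; escalating diagonal jitter if
# clipping alone fails.
spd_repair <- function(C, min_eig = 1e-6, max_iter = 50, state = NA) {
  C0 <- C
  floor_val <- max(min_eig, 1e-2)
  jitter <- 0
  for (it in seq_len(max_iter)) {
    e <- eigen(C, symmetric = TRUE)
    if (min(e$values) >= min_eig && max(abs(diag(C) - 1)) < 1e-12) break
    vals <- pmax(e$values, floor_val) + jitter
    C <- e$vectors %*% (vals * t(e$vectors))
    C <- stats::cov2cor(C)
    C <- (C + t(C)) / 2
    if (it > 10) jitter <- max(jitter * 10, 1e-6)
  }
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < min_eig)
    stop_dynfc("SPD repair failed for state %s", state)
  attr(C, "repair_distance") <- norm(C - C0, "F")
  C
}

#' Build SPD state correlation matrices from block designs
#'
#' Places the signed block strengths into unit-diagonal matrices and
#' applies nearest-SPD repair (eigenvalue clipping at 1e-6 followed by
#' rescaling to unit diagonal) where a raw design is indefinite. The
#' Frobenius repair distance is attached as attribute `repair_distance`.
#'
#' @param spec a [synth_spec()] (only `n_networks`/`k_states` are used).
#' @param block_design list of per-state data frames `i`, `j`, `value` with
#'   strengths in (-1, 1).
#' @return list of SPD unit-diagonal matrices.
#' @export
build_state_covariances <- function(spec, block_design) {
  n <- spec$n_networks
  lapply(seq_along(block_design), function(s) {
    df <- block_design[[s]]
    C <- diag(n)
    if (nrow(df)) {
      if (any(abs(df$value) >= 1))
        stop_dynfc("block strengths must lie in (-1, 1) (state %d)", s)
      for (r in seq_len(nrow(df))) {
        C[df$i[r], df$j[r]] <- df$value[r]
        C[df$j[r], df$i[r]] <- df$value[r]
      }
    }
    e <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (e < 1e-6) C <- spd_repair(C, state = s)
    else attr(C, "repair_distance") <- 0
    C
  })
}
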