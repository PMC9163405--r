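test_that("state covariance construction yields SPD unit-diagonal matrices", {
  sp <- synth_spec()
  # identity blocks give identity matrices
  ident <- build_state_covariances(sp, list(data.frame(i = integer(),
                                                       j = integer(),
                                                       value = numeric())))
  expect_equal(ident[[1]], diag(14), ignore_attr = TRUE)
  expect_equal(attr(ident[[1]], "repair_distance"), 0)

  # one 2-network block at +0.6: principal submatrix eigenvalues 1.6 / 0.4
  one <- build_state_covariances(sp, list(data.frame(i = 1, j = 2,
                                                     value = 0.6)))[[1]]
  expect_equal(eigen(one[1:2, 1:2], symmetric = TRUE)$values, c(1.6, 0.4),
               tolerance = 1e-12)

  # indefinite design (three mutual -0.9) is repaired to SPD
  bad <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), value = rep(-0.9, 3))
  rep3 <- build_state_covariances(sp, list(bad))[[1]]
  expect_gte(min(eigen(rep3, symmetric = TRUE, only.values = TRUE)$values),
             1e-6)
  expect_equal(diag(rep3), rep(1, 14), tolerance = 1e-10, ignore_attr = TRUE)
  expect_gt(attr(rep3, "repair_distance"), 0)

  # default states are SPD with unit diagonal
  for (C in sp$state_covariances) {
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
               1e-6)
    expect_equal(diag(C), rep(1, 14), tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(build_state_covariances(sp, list(data.frame(i = 1, j = 2,
                                                           value = 1.2))),
               "strengths")
})

test_that("subject simulation is seed-deterministic and honors degenerate limits", {
  sp <- small_spec(k = 2, n_networks = 5)
  a <- simulate_subject(sp, "HC", 42)
  b <- simulate_subject(sp, "HC", 42)
  expect_identical(a$tc$data, b$tc$data)
  expect_identical(a$truth$state_sequence, b$truth$state_sequence)
  c_ <- simulate_subject(sp, "HC", 43)
  expect_false(identical(a$tc$data, c_$tc$data))

  # identity transition matrix freezes the chain
  I2 <- diag(2)
  spI <- synth_spec(n_networks = 5, n_timepoints = 50, k_states = 2,
                    block_design = sp$block_design[1:2],
                    transition_matrix_per_group =
                      list(HC = I2, HD = I2, NonD = I2),
                    initial_distribution = c(0.5, 0.5), edge_effects = list())
  simI <- simulate_subject(spI, "HC", 7)
  expect_equal(simI$truth$n_switches, 0)
  expect_equal(length(unique(simI$truth$state_sequence)), 1L)

  expect_error(simulate_subject(sp, "XX", 1), "unknown group")
})

test_that("a long single-state simulation reproduces its covariance", {
  design <- list(data.frame(i = c(1, 2), j = c(3, 4),
                            value = c(0.6, -0.5)))
  sp <- synth_spec(n_networks = 4, n_timepoints = 20000, k_states = 1,
                   block_design = design,
                   transition_matrix_per_group =
                     list(HC = matrix(1, 1, 1)),
                   initial_distribution = 1,
                   edge_effects = list(), noise_sd = 0, ar_coeff = 0)
  sim <- simulate_subject(sp, "HC", 5)
  S <- cov(sim$tc$data)
  expect_lt(max(abs(S - sp$state_covariances[[1]])), 0.05)
})

test_that("two-state symmetric switching visits both states evenly", {
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  sp <- synth_spec(n_networks = 4, n_timepoints = 170, k_states = 2,
                   block_design = list(
                     data.frame(i = 1, j = 2, value = 0.6),
                     data.frame(i = 3, j = 4, value = 0.6)),
                   transition_matrix_per_group = list(HC = P),
                   initial_distribution = c(0.5, 0.5), edge_effects = list())
  occ <- rowMeans(vapply(1:200, function(s)
    simulate_subject(sp, "HC", s)$truth$occupancy, numeric(2)))
  expect_lt(max(abs(occ - 0.5)), 0.15)
})

test_that("edge effects weaken exactly the targeted covariance entries", {
  sp <- synth_spec()
  covs_hc <- dynfc:::group_state_covariances(sp, "HC")
  covs_hd <- dynfc:::group_state_covariances(sp, "HD")
  ef <- sp$edge_effects[[2]]  # the HD effect
  expect_identical(ef$group, "HD")
  # unaffected states identical
  for (s in setdiff(1:4, ef$state))
    expect_identical(covs_hc[[s]], covs_hd[[s]])
  # a factor of 1 is a bit-for-bit no-op
  sp1 <- sp
  sp1$edge_effects <- lapply(sp$edge_effects, function(e) {
    e$factor <- 1
    e
  })
  simA <- simulate_subject(sp1, "HD", 3)
  sp0 <- sp
  sp0$edge_effects <- list()
  simB <- simulate_subject(sp0, "HD", 3)
  expect_identical(simA$tc$data, simB$tc$data)
})

test_that("cohorts have the right size, schema and noise-free cognition is exactly linear", {
  sp <- small_spec(k = 2, n_networks = 5, n_timepoints = 60)
  cohort <- simulate_cohort(sp, c(HD = 2, NonD = 2, HC = 3), seed = 9)
  expect_length(cohort$timecourses, 7)
  expect_equal(nrow(cohort$covariates), 7)
  expect_true(all(c("subject_id", "group", "age", "sex", "education",
                    "mean_fd", "disease_duration", "TMT_A", "MMSE")
                  %in% names(cohort$covariates)))
  expect_true(all(is.na(
    cohort$covariates$disease_duration[cohort$covariates$group == "HC"])))
  expect_true(all(cohort$covariates$mean_fd >= 0))

  # different master seeds: different data, same schema
  cohort2 <- simulate_cohort(sp, c(HD = 2, NonD = 2, HC = 3), seed = 10)
  expect_false(identical(cohort$timecourses[[1]]$data,
                         cohort2$timecourses[[1]]$data))
  expect_identical(names(cohort$covariates), names(cohort2$covariates))

  # zero-noise cognition equals the configured linear model exactly
  cog <- cognition_config()
  for (nm in names(cog)) cog[[nm]]$sd <- 0
  one <- simulate_cohort(sp, c(HC = 1), seed = 4, cognition = cog)
  m <- cog$TMT_A
  want <- m$intercept + m$b_trans * one$truth[[1]]$n_switches +
    m$b_occ3 * 0  # only 2 states here; occupancy_3 treated as 0
  got <- one$covariates$TMT_A
  k <- length(one$truth[[1]]$occupancy)
  occ3 <- if (k >= 3) one$truth[[1]]$occupancy[3] else 0
  expect_equal(got, round(m$intercept + m$b_trans *
                            one$truth[[1]]$n_switches + m$b_occ3 * occ3, 1))

  expect_error(simulate_cohort(sp, c(2, 2)), "named")
})

test_that("ground-truth windowed labels use majority vote with lowest-index ties", {
  wspec <- tapered_window_spec(22)
  # constant sequence
  gt <- ground_truth_temporal_metrics(list(state_sequence = rep(2, 100)),
                                      wspec, k_states = 3)
  expect_equal(gt$metrics$fractional_windows[2], 1)
  expect_equal(gt$metrics$n_transitions, 0L)

  # [1 x 85, 2 x 85]: exactly one transition in the windowed labels
  gt2 <- ground_truth_temporal_metrics(
    list(state_sequence = rep(1:2, each = 85)), wspec, k_states = 2)
  expect_equal(gt2$metrics$n_transitions, 1L)
  # brute-force majority oracle
  s <- rep(1:2, each = 85)
  oracle <- vapply(1:(170 - 22), function(st) {
    cnt <- c(sum(s[st:(st + 21)] == 1), sum(s[st:(st + 21)] == 2))
    which.max(cnt)
  }, 0L)
  expect_equal(gt2$window_labels, oracle)

  # alternating labels: every window ties 11-11, resolved to state 1
  alt <- rep(1:2, 60)
  gt3 <- ground_truth_temporal_metrics(list(state_sequence = alt), wspec,
                                       k_states = 2)
  expect_true(all(gt3$window_labels == 1L))

  expect_error(ground_truth_temporal_metrics(
    list(state_sequence = rep(1, 10)), wspec, k_states = 2), "exceed")
})

test_that("long-run occupancies converge to the stationary distribution", {
  P <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, byrow = TRUE)
  pi_stat <- c(1 / 3, 2 / 3)  # solves pi P = pi
  sp <- synth_spec(n_networks = 3, n_timepoints = 5000, k_states = 2,
                   block_design = list(
                     data.frame(i = 1, j = 2, value = 0.5),
                     data.frame(i = 2, j = 3, value = 0.5)),
                   transition_matrix_per_group = list(HC = P),
                   initial_distribution = c(0.5, 0.5), edge_effects = list())
  occ <- rowMeans(vapply(1:10, function(s)
    simulate_subject(sp, "HC", s)$truth$occupancy, numeric(2)))
  expect_lt(max(abs(occ - pi_stat)), 0.05)
})
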