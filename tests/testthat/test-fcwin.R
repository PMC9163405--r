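test_that("window counts follow the drop-last convention", {
  expect_equal(make_tapered_windows(170, tapered_window_spec(22))$n_windows,
               148)
  expect_equal(make_tapered_windows(170, tapered_window_spec(20))$n_windows,
               150)
  expect_equal(make_tapered_windows(170, tapered_window_spec(30))$n_windows,
               140)
  expect_equal(
    make_tapered_windows(170, tapered_window_spec(
      22, count_convention = "n_minus_w_plus_1"))$n_windows, 149)
  expect_error(make_tapered_windows(20, tapered_window_spec(22)), "exceed")
})

test_that("taper weights are nonnegative, symmetric, normalized, and tend to the rectangle as sigma -> 0", {
  for (W in c(20, 22, 30)) {
    w <- make_tapered_windows(170, tapered_window_spec(W, 3))$weights
    expect_length(w, W)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, rev(w), tolerance = 1e-12)
  }
  w0 <- make_tapered_windows(170, tapered_window_spec(22, 0.01))$weights
  expect_lt(max(abs(w0 - 1 / 22)), 1e-3)
})

test_that("static FC applies Fisher r-to-z with clipping", {
  tc <- make_tc(100, 4, seed = 5)
  z <- static_fc(tc)
  expect_equal(z, t(z))
  expect_equal(diag(z), rep(0, 4), ignore_attr = TRUE)
  expect_equal(z[1, 2], atanh(cor(tc$data[, 1], tc$data[, 2])),
               tolerance = 1e-12)

  # identical columns: r clipped so z stays finite
  tc2 <- timecourse(cbind(tc$data[, 1], tc$data[, 1]), c("a", "b"))
  z2 <- static_fc(tc2)
  expect_true(is.finite(z2[1, 2]))
  expect_equal(z2[1, 2], atanh(1 - 1e-7))

  # exactly orthogonal mean-centered columns give z = 0
  x <- c(1, -1, 1, -1, 1, -1)
  y <- c(1, 1, -1, -1, 1, -1) * c(1, 1, 1, 1, -1, 1)  # orthogonalized below
  y <- y - x * sum(x * y) / sum(x * x)
  y <- y - mean(y); x <- x - mean(x)
  tc3 <- timecourse(cbind(x, y), c("a", "b"))
  expect_equal(static_fc(tc3)[1, 2], 0, tolerance = 1e-12)

  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  tc4 <- timecourse(cbind(rep(1, 10), rnorm(10)), c("const", "b"))
  expect_error(static_fc(tc4), "const")
})

test_that("weighted window covariance matches a two-pass oracle", {
  tc <- make_tc(40, 5, seed = 6)
  W <- 22
  set.seed(8)
  w <- runif(W); w <- w / sum(w)
  S <- weighted_window_covariance(tc, w, start = 3)

  X <- tc$data[3:(3 + W - 1), ]
  mu <- colSums(X * w)
  oracle <- matrix(0, 5, 5)
  for (t in seq_len(W))
    oracle <- oracle + w[t] * tcrossprod(X[t, ] - mu)
  expect_equal(S, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # uniform weights equal the 1/W-normalized sample covariance
  Su <- weighted_window_covariance(tc, rep(1 / W, W), 1)
  Xc <- scale(tc$data[1:W, ], scale = FALSE)
  expect_equal(Su, crossprod(Xc) / W, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(weighted_window_covariance(tc, c(1, rep(0, W - 1))),
               "degenerate")
})

test_that("graphical lasso reduces to the inverse at rho 0 and matches the 2x2 closed form", {
  set.seed(10)
  A <- matrix(rnorm(30), 10, 3)
  S <- crossprod(A) / 10 + diag(3) * 0.5
  f0 <- graphical_lasso(S, 0)
  expect_lt(max(abs(f0$theta - solve(S))), 1e-8)

  # large penalty: diagonal precision
  fL <- graphical_lasso(S, max(abs(S - diag(diag(S)))) * 1.5)
  expect_lt(max(abs(fL$theta[upper.tri(S)])), 1e-8)

  # 2x2 closed form: soft-thresholded covariance
  for (s in c(-0.7, 0.2, 0.6)) {
    for (rho in c(0.05, 0.3)) {
      S2 <- matrix(c(1, s, s, 1), 2)
      fit <- graphical_lasso(S2, rho)
      m <- sign(s) * max(abs(s) - rho, 0)
      expect_equal(fit$theta[1, 2], -m / ((1 + rho)^2 - m^2),
                   tolerance = 1e-7)
      expect_equal(fit$w[1, 2], m, tolerance = 1e-7)
    }
  }
})

test_that("glasso precision stays PD and its support shrinks with the penalty", {
  set.seed(13)
  A <- matrix(rnorm(8 * 30), 30, 8)
  S <- cor(A)
  prev_support <- Inf
  for (rho in c(0, 0.05, 0.1, 0.2, 0.4)) {
    fit <- graphical_lasso(S, rho)
    ev <- eigen(fit$theta, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    supp <- sum(abs(fit$theta[upper.tri(S)]) > 1e-8)
    expect_lte(supp, prev_support)
    prev_support <- supp
  }
})

test_that("penalty selection is deterministic and prefers shrinkage for noisy sparse data", {
  # few noisy windows from a sparse precision: held-out likelihood favors
  # a positive penalty
  set.seed(21)
  Theta <- diag(6)
  Theta[1, 2] <- Theta[2, 1] <- 0.4
  Sigma <- solve(Theta)
  picks <- vapply(1:20, function(s) {
    set.seed(s)
    covs <- lapply(1:10, function(i) {
      X <- MASS::mvrnorm(12, rep(0, 6), Sigma)
      crossprod(scale(X, scale = FALSE)) / 12
    })
    select_penalty(covs, glasso_config(penalty_grid = c(0, 0.05, 0.1, 0.2),
                                       n_repeats = 20), seed = s)
  }, 0)
  expect_gte(mean(picks > 0), 0.8)

  covs <- lapply(1:5, function(i) diag(3))
  expect_identical(select_penalty(covs, glasso_config(penalty_grid = 0)), 0)
  # duplicated grid values collapse to the unique grid
  cfg_dup <- glasso_config(penalty_grid = c(0.1, 0.1, 0.05))
  expect_equal(cfg_dup$penalty_grid, c(0.05, 0.1))
  # determinism
  set.seed(30)
  covs2 <- lapply(1:8, function(i) cor(matrix(rnorm(60), 20, 3)))
  p1 <- select_penalty(covs2, glasso_config(n_repeats = 10), seed = 5)
  p2 <- select_penalty(covs2, glasso_config(n_repeats = 10), seed = 5)
  expect_identical(p1, p2)
})

test_that("dynamic FC has the right geometry and is consistent with static FC", {
  tc <- make_tc(170, 14, seed = 14)
  st <- dynamic_fc(tc, gcfg = glasso_config(penalty_grid = 0.05))
  expect_s3_class(st, "fc_stack")
  expect_equal(dim(st$edge_values), c(148, 91))
  expect_true(all(is.finite(st$edge_values)))

  # single full-length rectangle window at rho = 0 reproduces static FC
  T_ <- 40
  tc2 <- make_tc(T_ + 1, 5, seed = 15)
  wspec <- tapered_window_spec(window_length_tr = T_, taper_sigma_tr = 0.01)
  st2 <- dynamic_fc(tc2, wspec, glasso_config(penalty_grid = 0))
  z_static <- mat_to_edges(static_fc(
    timecourse(tc2$data[1:T_, ], tc2$network_labels)))
  expect_equal(as.numeric(st2$edge_values[1, ]), z_static, tolerance = 1e-2)

  # determinism end to end
  stA <- dynamic_fc(tc, gcfg = glasso_config(n_repeats = 5), seed = 9)
  stB <- dynamic_fc(tc, gcfg = glasso_config(n_repeats = 5), seed = 9)
  expect_identical(stA$edge_values, stB$edge_values)
})

test_that("edge variability shrinks with longer windows in a single-state simulation", {
  sp <- small_spec(k = 1, n_networks = 5, n_timepoints = 150)
  sim <- simulate_subject(sp, "HC", 33)
  sd20 <- apply(dynamic_fc(sim$tc, tapered_window_spec(20),
                           glasso_config(penalty_grid = 0))$edge_values,
                2, sd)
  sd30 <- apply(dynamic_fc(sim$tc, tapered_window_spec(30),
                           glasso_config(penalty_grid = 0))$edge_values,
                2, sd)
  expect_gt(mean(sd20 > sd30), 0.8)
})

test_that("covariate residualization matches a per-cell regression oracle", {
  set.seed(40)
  n_sub <- 12
  covs <- data.frame(age = rnorm(n_sub, 40, 10), sex = rbinom(n_sub, 1, .5),
                     education = rnorm(n_sub, 12, 3),
                     mean_fd = runif(n_sub, 0.01, 0.2))
  stacks <- lapply(seq_len(n_sub), function(i) {
    structure(list(subject_id = paste0("s", i),
                   edge_values = matrix(rnorm(5 * 6), 5, 6),
                   n_windows = 5L, network_labels = paste0("N", 1:4)),
              class = "fc_stack")
  })
  out <- residualize_covariates(stacks, covs)
  # oracle: per-cell lm residual + intercept at covariate mean
  X <- scale(as.matrix(covs))
  for (cell in list(c(1, 1), c(3, 4), c(5, 6))) {
    y <- vapply(stacks, function(s) s$edge_values[cell[1], cell[2]], 0)
    fit <- lm(y ~ X)
    oracle <- resid(fit) + coef(fit)[1]
    got <- vapply(out, function(s) s$edge_values[cell[1], cell[2]], 0)
    expect_equal(got, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  }

  # constant covariates: only the intercept is fitted, data unchanged
  covs2 <- covs
  covs2$age <- 5; covs2$sex <- 1; covs2$education <- 2; covs2$mean_fd <- 0.1
  out2 <- residualize_covariates(stacks, covs2)
  expect_equal(out2[[3]]$edge_values, stacks[[3]]$edge_values,
               tolerance = 1e-10)

  # edge exactly linear in age: residual variance collapses to zero
  stacks3 <- stacks
  for (i in seq_len(n_sub))
    stacks3[[i]]$edge_values[2, 2] <- 0.3 * covs$age[i] - 1
  out3 <- residualize_covariates(stacks3, covs)
  v <- vapply(out3, function(s) s$edge_values[2, 2], 0)
  expect_lt(var(v), 1e-10)

  expect_error(residualize_covariates(stacks, covs[, 1:2]), "missing")
})

test_that("Fisher z is odd and monotone", {
  r <- seq(-0.95, 0.95, by = 0.05)
  z <- atanh(r)
  expect_equal(z, -rev(z), tolerance = 1e-12)
  expect_true(all(diff(z) > 0))
})
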