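test_that("RBME covariance matches its printed definition", {
  G <- rbme_covariance(2, D = 1.0, loc_error_var = 0.0009, dt = 0.00748)
  expect_equal(G, matrix(c(0.01676, -0.0009, -0.0009, 0.01676), 2),
               tolerance = 1e-12)
  # no localization error: independent jumps (Markov limit)
  G0 <- rbme_covariance(5, D = 2, loc_error_var = 0, dt = 0.01)
  expect_equal(G0, diag(2 * 2 * 0.01, 5))
  # generic banded-constructor oracle
  L <- 4
  Go <- matrix(0, L, L)
  for (i in 1:L) for (j in 1:L)
    Go[i, j] <- if (i == j) 2 * (2 * 0.01 + 0.0016) else
      if (abs(i - j) == 1) -0.0016 else 0
  expect_equal(rbme_covariance(L, 2, 0.0016, 0.01), Go)
})

test_that("RBME log-likelihood agrees with a generic MVN oracle", {
  # single zero jump with D*dt + sigma2 = 0.5: density 1/(2*pi)
  expect_equal(rbme_log_likelihood(0, 0, D = 0.5, loc_error_var = 0, dt = 1),
               -log(2 * pi), tolerance = 1e-12)
  set.seed(11)
  for (rep in 1:50) {
    L <- sample(1:8, 1)
    D <- runif(1, 0.01, 10)
    s2 <- runif(1, 0, 0.004)
    dt <- runif(1, 0.002, 0.02)
    dx <- rnorm(L, sd = 0.2)
    dy <- rnorm(L, sd = 0.2)
    expect_equal(rbme_log_likelihood(dx, dy, D, s2, dt),
                 rbme_oracle(dx, dy, D, s2, dt), tolerance = 1e-8)
  }
})

test_that("zero localization error reduces to independent jump densities", {
  set.seed(2)
  dx <- rnorm(5, sd = 0.2); dy <- rnorm(5, sd = 0.2)
  D <- 3; dt <- 0.00748
  markov <- sum(dnorm(dx, 0, sqrt(2 * D * dt), log = TRUE) +
                dnorm(dy, 0, sqrt(2 * D * dt), log = TRUE))
  expect_equal(rbme_log_likelihood(dx, dy, D, 0, dt), markov,
               tolerance = 1e-10)
})

test_that("gamma log-likelihood matches direct substitution", {
  expect_equal(gamma_log_likelihood(0.12, 3, log(0.04)),
               -0.12 / 0.04 - 3 * log(0.04), tolerance = 1e-12)
  expect_equal(gamma_log_likelihood(0, 5, 1.7), -5 * 1.7)
})

test_that("gamma and RBME likelihoods share their argmax when sigma2 = 0", {
  set.seed(3)
  dt <- 0.00748
  dx <- rnorm(20, sd = sqrt(2 * 1.5 * dt))
  dy <- rnorm(20, sd = sqrt(2 * 1.5 * dt))
  S <- sum(dx^2 + dy^2); L <- length(dx)
  # closed-form argmax of the gamma likelihood: phi* = log(S / L)
  phis <- seq(-9, -2, length.out = 2000)
  g <- gamma_log_likelihood(S, L, phis)
  expect_equal(phis[which.max(g)], log(S / L), tolerance = 0.01)
  # grid scan of the full RBME likelihood over D agrees with the MSD
  Ds <- exp(seq(log(0.05), log(20), length.out = 2000))
  ll <- vapply(Ds, function(D) rbme_log_likelihood(dx, dy, D, 0, dt),
               numeric(1))
  D_msd <- S / (4 * L * dt)
  expect_equal(Ds[which.max(ll)], D_msd, tolerance = 0.01)
  # and the two maximizers describe the same state: phi* = log(4 D* dt)
  expect_equal(log(S / L), log(4 * D_msd * dt), tolerance = 1e-12)
})

test_that("FBME increment covariance matches printed forms", {
  # H = 1/2 is Brownian: off-diagonal fBm term vanishes
  for (s2 in c(0, 0.0012)) {
    expect_equal(fbme_increment_covariance(6, 2.5, 0.5, s2, 0.00748),
                 rbme_covariance(6, 2.5, s2, 0.00748), tolerance = 1e-12)
  }
  # direct substitution at L=2, H=0.3, sigma2=0, 2*S*dt = 1
  dt <- 0.01
  sbar <- 0.5 / dt
  G <- fbme_increment_covariance(2, sbar, 0.3, 0, dt)
  expect_equal(G[1, 1], 1, tolerance = 1e-12)
  expect_equal(G[1, 2], 0.5 * (2^0.6 - 2), tolerance = 1e-12)
  # jump variance 2*Sbar*dt + 2*sigma2 independent of the Hurst parameter
  for (H in c(0.2, 0.5, 0.8)) {
    G <- fbme_increment_covariance(4, 3, H, 0.001, 0.00748)
    expect_equal(diag(G), rep(2 * 3 * 0.00748 + 2 * 0.001, 4),
                 tolerance = 1e-12)
  }
})

test_that("FBME log-likelihood equals RBME at H = 0.5", {
  set.seed(5)
  for (L in c(1, 3, 7)) {
    dx <- rnorm(L, sd = 0.2); dy <- rnorm(L, sd = 0.2)
    expect_equal(fbme_log_likelihood(dx, dy, 1.7, 0.5, 0.0009, 0.00748),
                 rbme_log_likelihood(dx, dy, 1.7, 0.0009, 0.00748),
                 tolerance = 1e-10)
  }
})

test_that("likelihood matrix rows are normalized and duplicates identical", {
  set.seed(6)
  ds <- make_rbme_ds(30, 5, D = 1, sigma_loc = 0.03)
  grid <- parameter_grid(diffusion_values = c(0.1, 1, 1, 10),
                         loc_error_values = c(0, 0.03))
  lik <- evaluate_grid(ds, grid)
  expect_equal(rowSums(lik$A), rep(1, 30), tolerance = 1e-9)
  # duplicated D value -> identical columns (for each sigma level)
  expect_equal(lik$A[, 2], lik$A[, 3])
  expect_true(all(is.finite(lik$A)) && all(lik$A >= 0))
})

test_that("the generating state wins the likelihood for long trajectories", {
  grid <- parameter_grid(diffusion_values = c(0.5, 5),
                         loc_error_values = 0.03)
  set.seed(7)
  wins <- 0L
  n_seeds <- 200L
  for (i in seq_len(n_seeds)) {
    ds <- make_rbme_ds(1, 51, D = 5, sigma_loc = 0.03)
    lik <- evaluate_grid(ds, grid)
    if (which.max(lik$A[1, ]) == 2L) wins <- wins + 1L
  }
  expect_gt(wins / n_seeds, 0.95)
})

test_that("sequential-jump covariance of RBME data is about -sigma2", {
  set.seed(8)
  ds <- make_rbme_ds(400, 26, D = 1, sigma_loc = 0.04)
  j <- trajectory_jumps(ds)
  n <- nrow(j)
  within <- j$trajectory[-1] == j$trajectory[-n]
  prods <- c((j$dx[-1] * j$dx[-n])[within], (j$dy[-1] * j$dy[-n])[within])
  se <- sd(prods) / sqrt(length(prods))
  expect_lt(abs(mean(prods) - (-0.04^2)), 3 * se)
})

test_that("degenerate grid vertices are zeroed, not fatal", {
  set.seed(9)
  ds <- make_rbme_ds(5, 5, D = 1, sigma_loc = 0.03)
  grid <- parameter_grid(diffusion_values = c(0, 1),
                         loc_error_values = c(0, 0.03))
  lik <- evaluate_grid(ds, grid)
  # vertex D=0, sigma=0 has zero likelihood for every trajectory
  k_degen <- which(grid$states$D == 0 & grid$states$sigma_loc == 0)
  expect_equal(unname(lik$A[, k_degen]), rep(0, 5))
  expect_true(k_degen %in% lik$degenerate_states)
})
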