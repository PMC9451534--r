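# Shared fixtures and independent oracles, built in code at test time.

default_acq <- function(...) acquisition_params(...)

# Build a dataset directly from a detections data.frame.
make_ds <- function(df, acq = default_acq(), unit = "um") {
  trajectory_dataset(df, acq, unit = unit)
}

# One-trajectory dataset from explicit positions (um).
make_traj_ds <- function(x, y, frames = seq_along(x) - 1L,
                         acq = default_acq()) {
  make_ds(data.frame(trajectory = 1L, frame = frames, x = x, y = y), acq)
}

# Dataset of n pure-RBME trajectories of n_pos positions each, generated
# directly from the definition (cumulative Gaussian steps plus iid
# positional noise) — independent of the package's simulator.
make_rbme_ds <- function(n, n_pos, D, sigma_loc, dt = 0.00748,
                         acq = acquisition_params(frame_interval = dt)) {
  dfs <- lapply(seq_len(n), function(i) {
    x <- cumsum(c(0, stats::rnorm(n_pos - 1, sd = sqrt(2 * D * dt)))) +
      stats::rnorm(n_pos, sd = sigma_loc)
    y <- cumsum(c(0, stats::rnorm(n_pos - 1, sd = sqrt(2 * D * dt)))) +
      stats::rnorm(n_pos, sd = sigma_loc)
    data.frame(trajectory = i, frame = seq_len(n_pos) - 1L, x = x, y = y)
  })
  make_ds(do.call(rbind, dfs), acq)
}

# Generic multivariate-normal log density (solve + determinant), an
# implementation-independent oracle for the structured likelihoods.
mvn_log_density <- function(x, Sigma) {
  k <- length(x)
  q <- drop(crossprod(x, solve(Sigma, x)))
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  -0.5 * q - 0.5 * k * log(2 * pi) - 0.5 * as.numeric(ld)
}

# Brute-force RBME oracle: the 2L-dimensional Gaussian with
# block-diagonal covariance diag(Gamma, Gamma), Gamma built by a
# generic banded-matrix constructor.
rbme_oracle <- function(dx, dy, D, s2, dt) {
  L <- length(dx)
  G <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) G[i, j] <- 2 * (D * dt + s2)
    else if (abs(i - j) == 1) G[i, j] <- -s2
  }
  Sigma <- matrix(0, 2 * L, 2 * L)
  Sigma[1:L, 1:L] <- G
  Sigma[(L + 1):(2 * L), (L + 1):(2 * L)] <- G
  mvn_log_density(c(dx, dy), Sigma)
}

# Likelihood-matrix object from an explicit A matrix (for algebraic
# state-array tests with hand-chosen likelihoods).
make_lik <- function(A, L, grid = NULL) {
  if (is.null(grid))
    grid <- parameter_grid(
      diffusion_values = 10^seq(-1, 1, length.out = ncol(A)),
      loc_error_values = 0.03
    )
  structure(list(A = A, L = L, grid = grid, row_norm = FALSE,
                 degenerate_states = integer(0)),
            class = "sa_likelihood")
}

# Weighted empirical CDF distance between two weighted samples
# (used for the DPMM exchangeability check).
weighted_cdf_dist <- function(x1, w1, x2, w2) {
  grid <- sort(unique(c(x1, x2)))
  F1 <- c(0, cumsum(w1[order(x1)]) / sum(w1))[findInterval(grid, sort(x1)) + 1]
  F2 <- c(0, cumsum(w2[order(x2)]) / sum(w2))[findInterval(grid, sort(x2)) + 1]
  max(abs(F1 - F2))
}
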