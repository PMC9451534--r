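test_that("single-state array pins all responsibility on it", {
  A <- matrix(1, 5, 1)
  L <- c(2, 3, 1, 4, 5)
  lik <- make_lik(A, L, parameter_grid(diffusion_values = 1,
                                       loc_error_values = 0.03))
  post <- sa_infer(lik, alpha = 2)
  expect_equal(unname(post$r[, 1]), rep(1, 5))
  expect_equal(post$n, 2 + sum(L))
  expect_equal(occupations(post)$occupations, 1)
  expect_true(post$converged)
  expect_lte(post$iterations, 1L)
})

test_that("one-hot likelihoods weight occupations by jumps as alpha -> 0", {
  A <- rbind(matrix(rep(c(1, 0), 3), 3, byrow = TRUE), c(0, 1))
  L <- c(2, 2, 2, 6)
  lik <- make_lik(A, L)
  post <- sa_infer(lik, alpha = 1e-8, tol = 1e-12)
  expect_equal(occupations(post)$occupations, c(0.5, 0.5), tolerance = 1e-8)
})

test_that("naive occupations follow their printed definition", {
  # single trajectory with a normalized flat row
  lik1 <- make_lik(matrix(c(0.5, 0.5), 1), L = 4)
  expect_equal(naive_occupations(lik1)$occupations, c(0.5, 0.5))
  # two rows: [1,0] with L=2 and [.5,.5] with L=2 -> (0.75, 0.25)
  lik2 <- make_lik(rbind(c(1, 0), c(0.5, 0.5)), L = c(2, 2))
  expect_equal(naive_occupations(lik2)$occupations, c(0.75, 0.25))
  # definitional: equals the posterior occupations after zero updates
  # (in the weak-prior limit)
  set.seed(21)
  A <- matrix(runif(60), 10, 6)
  A <- A / rowSums(A)
  lik <- make_lik(A, L = sample(1:6, 10, replace = TRUE),
                  grid = parameter_grid(
                    diffusion_values = 10^seq(-1, 1, length.out = 6),
                    loc_error_values = 0.03))
  post0 <- sa_infer(lik, alpha = 1e-10, max_iter = 0)
  expect_equal(occupations(post0)$occupations,
               naive_occupations(lik)$occupations, tolerance = 1e-8)
})

test_that("converged posteriors satisfy the fixed-point equations", {
  set.seed(22)
  N <- 60; K <- 8
  A <- matrix(rexp(N * K), N, K)
  A <- A / rowSums(A)
  L <- sample(1:8, N, replace = TRUE)
  lik <- make_lik(A, L, parameter_grid(
    diffusion_values = 10^seq(-1, 1, length.out = K),
    loc_error_values = 0.03))
  post <- sa_infer(lik, alpha = 2, max_iter = 20000, tol = 1e-13)
  expect_true(post$converged)
  n2 <- 2 / K + colSums(post$r * L)
  expect_lt(max(abs(n2 - post$n)), 1e-6)
  w <- exp(digamma(n2))
  r2 <- t(t(A) * w)
  r2 <- r2 / rowSums(r2)
  expect_lt(max(abs(r2 - post$r)), 1e-8)
  # pseudocount bookkeeping invariants
  expect_true(all(post$n >= 2 / K - 1e-12))
  expect_equal(sum(post$n), 2 + sum(L), tolerance = 1e-6)
  expect_equal(rowSums(post$r), rep(1, N), tolerance = 1e-9)
})

test_that("duplicating every trajectory sharpens n but leaves E[tau] fixed", {
  set.seed(23)
  A <- matrix(rexp(40 * 5), 40, 5)
  A <- A / rowSums(A)
  L <- sample(1:5, 40, replace = TRUE)
  g <- parameter_grid(diffusion_values = 10^seq(-1, 1, length.out = 5),
                      loc_error_values = 0.03)
  p1 <- sa_infer(make_lik(A, L, g), alpha = 1e-6, tol = 1e-12,
                 max_iter = 20000)
  p2 <- sa_infer(make_lik(rbind(A, A), c(L, L), g), alpha = 1e-6,
                 tol = 1e-12, max_iter = 20000)
  t1 <- occupations(p1)$occupations
  t2 <- occupations(p2)$occupations
  # E[tau] is invariant up to the O(1/n) digamma correction
  expect_lt(max(abs(t1 - t2)), 0.02)
  expect_gt(sum(p2$n), 1.9 * sum(p1$n))
})

test_that("marginalizing localization error conserves mass", {
  g <- parameter_grid(diffusion_values = c(0.1, 1),
                      loc_error_values = c(0, 0.03, 0.06))
  # uniform occupations on the 2x3 grid -> (0.5, 0.5) over D
  prof <- statearray:::new_profile(g$states, rep(1 / 6, 6), "RBME")
  m <- marginalize_loc_error(prof)
  expect_equal(m$occupations, c(0.5, 0.5))
  expect_equal(m$states$D, c(0.1, 1))
  # random occupations: exact mass conservation
  set.seed(24)
  occ <- runif(6); occ <- occ / sum(occ)
  prof2 <- statearray:::new_profile(g$states, occ, "RBME")
  expect_equal(sum(marginalize_loc_error(prof2)$occupations), sum(occ),
               tolerance = 1e-12)
  # FBME grid: marginal is 2D over (D, hurst), mass preserved
  gf <- parameter_grid(diffusion_values = c(0.1, 1),
                       loc_error_values = c(0, 0.03),
                       hurst_values = c(0.3, 0.5))
  occf <- runif(gf$K); occf <- occf / sum(occf)
  mf <- marginalize_loc_error(statearray:::new_profile(gf$states, occf, "FBME"))
  expect_equal(sum(mf$occupations), sum(occf), tolerance = 1e-12)
  expect_true(all(c("D", "hurst") %in% names(mf$states)))
  # 1D profile passes through with a warning
  p1 <- statearray:::new_profile(data.frame(D = c(0.1, 1)), c(0.3, 0.7),
                                 "RBME")
  expect_warning(m1 <- marginalize_loc_error(p1), "no localization-error")
  expect_equal(m1$occupations, c(0.3, 0.7))
})

test_that("range integration is half-open and partitions mass", {
  prof <- statearray:::new_profile(data.frame(D = c(0.02, 0.5, 5, 50)),
                                   c(0.2, 0.3, 0.4, 0.1), "RBME",
                                   marginal = TRUE)
  expect_equal(occupation_in_range(prof, 0, Inf), 1.0)
  delta <- statearray:::new_profile(data.frame(D = 0.02), 1, "RBME",
                                    marginal = TRUE)
  expect_equal(occupation_in_range(delta, 0, 0.08), 1.0)
  parts <- c(occupation_in_range(prof, 0, 0.08),
             occupation_in_range(prof, 0.08, 1.5),
             occupation_in_range(prof, 1.5, 40))
  expect_equal(sum(parts), occupation_in_range(prof, 0, 40))
  # boundary vertex belongs to the upper range
  edge <- statearray:::new_profile(data.frame(D = 0.08), 1, "RBME",
                                   marginal = TRUE)
  expect_warning(lo <- occupation_in_range(edge, 0, 0.08), "no grid states")
  expect_equal(lo, 0)
  expect_equal(occupation_in_range(edge, 0.08, 1.5), 1)
})

test_that("mean free diffusion averages the mobile mass only", {
  mk <- function(D, occ) statearray:::new_profile(data.frame(D = D), occ,
                                                  "RBME", marginal = TRUE)
  expect_equal(mean_free_diffusion(mk(8, 1)), 8)
  expect_equal(mean_free_diffusion(mk(c(2, 4), c(0.5, 0.5))), 3)
  expect_equal(mean_free_diffusion(mk(c(0.01, 1), c(0.7, 0.3))), 1)
  expect_error(mean_free_diffusion(mk(0.01, 1)), "threshold")
  expect_equal(immobile_fraction(mk(c(0.01, 1), c(0.7, 0.3))), 0.7)
})

test_that("posterior mass concentrates at the true state for one-state data", {
  set.seed(25)
  # 5000 short trajectories from a single RBME state
  ds <- make_rbme_ds(5000, 5, D = 1, sigma_loc = 0.035)
  lik <- evaluate_grid(ds, parameter_grid())
  post <- sa_infer(lik)
  m <- marginalize_loc_error(occupations(post))
  Dax <- m$states$D
  # mode lands on the true vertex and >= 95% of the mass lies within
  # two grid spacings (+/- 0.08 decades) of the truth
  expect_equal(Dax[which.max(m$occupations)], 1, tolerance = 1e-9)
  spacing <- diff(log10(Dax))[1]
  near <- abs(log10(Dax) - log10(1)) <= 2 * spacing * 1.0001
  expect_gte(sum(m$occupations[near]), 0.95)
})

test_that("occupations are insensitive to the prior concentration", {
  set.seed(26)
  ds <- make_rbme_ds(1500, 5, D = 0.8, sigma_loc = 0.035)
  lik <- evaluate_grid(ds, parameter_grid())
  ranges <- list(c(0, 0.08), c(0.08, 1.5), c(1.5, 40))
  est <- sapply(c(0.5, 5), function(al) {
    m <- marginalize_loc_error(occupations(sa_infer(lik, alpha = al)))
    vapply(ranges, function(r) occupation_in_range(m, r[1], r[2]),
           numeric(1))
  })
  expect_lt(max(abs(est[, 1] - est[, 2])), 0.02)
})
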