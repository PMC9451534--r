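test_that("per-trajectory posteriors marginalize to unit rows", {
  set.seed(61)
  ds <- make_rbme_ds(80, 5, D = 1, sigma_loc = 0.03)
  grid <- parameter_grid(diffusion_values = 10^seq(-1, 1, length.out = 11),
                         loc_error_values = c(0, 0.03, 0.06))
  post <- sa_infer(evaluate_grid(ds, grid))
  tp <- trajectory_posteriors(post)
  expect_equal(dim(tp), c(80, 11))
  expect_equal(rowSums(tp), rep(1, 80), tolerance = 1e-9)
  # single-state grid: every row is exactly 1
  g1 <- parameter_grid(diffusion_values = 1, loc_error_values = 0.03)
  tp1 <- trajectory_posteriors(sa_infer(evaluate_grid(ds, g1)))
  expect_equal(unname(tp1[, 1]), rep(1, 80))
})

test_that("jump-weighted mean of rows equals global occupations as alpha -> 0", {
  set.seed(62)
  ds <- make_rbme_ds(120, 5, D = 0.8, sigma_loc = 0.03)
  grid <- parameter_grid(diffusion_values = 10^seq(-1, 1, length.out = 9),
                         loc_error_values = c(0.01, 0.04))
  post <- sa_infer(evaluate_grid(ds, grid), alpha = 1e-10, tol = 1e-12,
                   max_iter = 20000)
  tp <- trajectory_posteriors(post)
  wmean <- colSums(tp * post$L) / sum(post$L)
  glob <- marginalize_loc_error(occupations(post))$occupations
  expect_equal(wmean, glob, tolerance = 1e-7)
})

test_that("spatial maps place posterior mass at trajectory anchors", {
  grid <- parameter_grid(diffusion_values = c(0.02, 5),
                         loc_error_values = 0.03)
  mk_post <- function(r, L) structure(
    list(r = r, n = colSums(r * L) + 0.5, grid = grid, L = L,
         converged = TRUE, iterations = 10L),
    class = "sa_posterior")
  ranges <- diffusion_ranges(slow = c(0, 0.08), fast = c(0.08, 40))
  # one trajectory, delta posterior on the slow state, anchored at origin
  ds1 <- make_traj_ds(c(0, 0.01, 0.02), c(0, 0.01, 0))
  post1 <- mk_post(matrix(c(1, 0), 1), 2)
  expect_warning(
    m1 <- spatial_occupation_map(ds1, post1, ranges, bandwidth = 0.1,
                                 cell = 0.05),
    "zero posterior weight")
  peak <- which(m1$density$slow == max(m1$density$slow), arr.ind = TRUE)
  expect_equal(m1$x[peak[1]], 0, tolerance = 0.051)
  expect_equal(m1$y[peak[2]], 0, tolerance = 0.051)
  expect_true(all(m1$density$fast == 0))
  expect_equal(max(m1$fraction$slow, na.rm = TRUE), 1)
  # 50/50 posteriors: fractions are 0.5 wherever density is supported
  set.seed(63)
  df <- data.frame(trajectory = rep(1:6, each = 2),
                   frame = rep(0:1, 6),
                   x = rep(runif(6, -1, 1), each = 2),
                   y = rep(runif(6, -1, 1), each = 2))
  ds2 <- make_ds(df)
  post2 <- mk_post(matrix(0.5, 6, 2), rep(1, 6))
  m2 <- spatial_occupation_map(ds2, post2, ranges)
  f <- m2$fraction$slow
  expect_equal(range(f, na.rm = TRUE), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("map densities equal the brute-force pairwise Gaussian sum", {
  set.seed(64)
  n <- 15
  df <- data.frame(trajectory = rep(seq_len(n), each = 2),
                   frame = rep(0:1, n),
                   x = rep(runif(n, 0, 2), each = 2),
                   y = rep(runif(n, 0, 2), each = 2))
  ds <- make_ds(df)
  grid <- parameter_grid(diffusion_values = c(0.02, 5),
                         loc_error_values = 0.03)
  r <- cbind(runif(n)); r <- cbind(r, 1 - r)
  post <- structure(list(r = r, n = colSums(r) + 0.5, grid = grid,
                         L = rep(1, n), converged = TRUE,
                         iterations = 5L), class = "sa_posterior")
  ranges <- diffusion_ranges(slow = c(0, 0.08), fast = c(0.08, 40))
  h <- 0.12
  m <- spatial_occupation_map(ds, post, ranges, bandwidth = h, cell = 0.11)
  w <- r[, 1]
  brute <- matrix(0, length(m$x), length(m$y))
  for (i in seq_len(n))
    brute <- brute + w[i] *
      outer(m$x, m$y, function(px, py)
        exp(-((px - ds$index$x0[i])^2 + (py - ds$index$y0[i])^2) /
              (2 * h^2)) / (2 * pi * h^2))
  expect_equal(m$density$slow, brute, tolerance = 1e-8)
})

test_that("normalized fractions are closed under range removal", {
  set.seed(65)
  n <- 10
  df <- data.frame(trajectory = rep(seq_len(n), each = 2),
                   frame = rep(0:1, n),
                   x = rep(runif(n), each = 2), y = rep(runif(n), each = 2))
  ds <- make_ds(df)
  grid <- parameter_grid(diffusion_values = c(0.02, 0.5, 5),
                         loc_error_values = 0.03)
  r <- matrix(runif(3 * n), n); r <- r / rowSums(r)
  post <- structure(list(r = r, n = colSums(r) + 0.5, grid = grid,
                         L = rep(1, n), converged = TRUE, iterations = 5L),
                    class = "sa_posterior")
  r3 <- diffusion_ranges(a = c(0, 0.08), b = c(0.08, 1.5), c = c(1.5, 40))
  r2 <- diffusion_ranges(a = c(0, 0.08), b = c(0.08, 1.5))
  m3 <- spatial_occupation_map(ds, post, r3, floor_frac = 0)
  m2 <- spatial_occupation_map(ds, post, r2, floor_frac = 0)
  # fractions sum to 1 across a partition
  tot <- m3$fraction$a + m3$fraction$b + m3$fraction$c
  expect_equal(range(tot, na.rm = TRUE), c(1, 1), tolerance = 1e-9)
  # renormalizing after removing range c equals the two-range map
  renorm <- m3$fraction$a / (m3$fraction$a + m3$fraction$b)
  expect_equal(renorm, m2$fraction$a, tolerance = 1e-9)
})

test_that("temporal blocks partition trajectories by starting frame", {
  set.seed(66)
  grid <- parameter_grid(diffusion_values = 10^seq(-2, 2, length.out = 21),
                         loc_error_values = c(0.02, 0.04))
  dt <- 0.00748
  mk_block <- function(ids, frame0, D) {
    do.call(rbind, lapply(ids, function(i) {
      x <- cumsum(c(0, rnorm(4, sd = sqrt(2 * D * dt)))) +
        rnorm(5, sd = 0.03)
      y <- cumsum(c(0, rnorm(4, sd = sqrt(2 * D * dt)))) +
        rnorm(5, sd = 0.03)
      data.frame(trajectory = i, frame = frame0 + (0:4), x = x, y = y)
    }))
  }
  ds <- make_ds(rbind(mk_block(1:60, 10L, 0.05), mk_block(61:120, 110L, 5)))
  tb <- temporal_naive_profile(ds, grid, block = 100L)
  expect_equal(tb$block, c(0, 1))
  expect_equal(tb$n_trajectories, c(60L, 60L))
  expect_equal(sum(tb$n_localizations), nrow(ds$positions))
  # block profiles peak near the generating state
  p0 <- tb$profile[[1]]; p1 <- tb$profile[[2]]
  expect_lt(p0$states$D[which.max(p0$occupations)], 0.3)
  expect_gt(p1$states$D[which.max(p1$occupations)], 1)
  # a trajectory starting exactly at frame 100 belongs to block 1
  ds_edge <- make_ds(mk_block(1:2, 100L, 1))
  tbe <- temporal_naive_profile(ds_edge, grid, block = 100L)
  expect_equal(tbe$block, 1)
  # one block reproduces the global naive profile
  ds_all <- make_ds(mk_block(1:30, 5L, 1))
  tba <- temporal_naive_profile(ds_all, grid, block = 1000L)
  glob <- marginalize_loc_error(naive_occupations(evaluate_grid(ds_all, grid)))
  expect_equal(tba$profile[[1]]$occupations, glob$occupations,
               tolerance = 1e-12)
})
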