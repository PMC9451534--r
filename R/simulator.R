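#' Discrete-state motion model for trajectory simulation
#'
#' @param D Diffusion coefficients of the states, um^2/s.
#' @param sigma_loc Per-state localization error (standard deviation per
#'   axis, um); recycled to the number of states.
#' @param occupation State occupations; must be nonnegative and sum
#'   to 1.
#' @return An object of class `sa_sim_model`.
#' @export
sim_state_model <- function(D, sigma_loc = 0.035, occupation = NULL) {
  ns <- length(D)
  if (is.null(occupation)) occupation <- rep(1 / ns, ns)
  sigma_loc <- rep_len(sigma_loc, ns)
  stopifnot(ns >= 1, all(D >= 0), all(sigma_loc >= 0),
            length(occupation) == ns, all(occupation >= 0))
  if (abs(sum(occupation) - 1) > 1e-9)
    stop("state occupations must sum to 1 (got ", sum(occupation), ")")
  structure(list(D = as.numeric(D), sigma_loc = as.numeric(sigma_loc),
                 occupation = as.numeric(occupation)),
            class = "sa_sim_model")
}

#' Observation geometry for trajectory simulation
#'
#' Defaults reproduce a typical stroboscopic sptPALM acquisition in a
#' mammalian nucleus: a 5 um sphere, a 0.7 um focal slab bisecting it,
#' 7.48 ms frame intervals and 14 Hz Poisson photobleaching.
#'
#' @param radius Confining sphere radius, um.
#' @param focal_depth Focal slab depth, um (must be < 2 * radius).
#' @param frame_interval Frame interval, seconds.
#' @param bleach_rate Photobleaching rate, Hz (exponential lifetimes).
#' @param n_trajectories Target number of trajectories with at least
#'   one jump.
#' @param movie_frames Length of the virtual movie; each particle
#'   photoactivates at a frame drawn uniformly from it.
#' @return An object of class `sa_sim_geometry`.
#' @export
sim_geometry <- function(radius = 5, focal_depth = 0.7,
                         frame_interval = 0.00748, bleach_rate = 14,
                         n_trajectories = 10000L, movie_frames = 10000L) {
  stopifnot(radius > 0, focal_depth > 0, focal_depth < 2 * radius,
            frame_interval > 0, bleach_rate > 0, n_trajectories >= 1,
            movie_frames >= 1)
  structure(list(radius = radius, focal_depth = focal_depth,
                 frame_interval = frame_interval, bleach_rate = bleach_rate,
                 n_trajectories = as.integer(n_trajectories),
                 movie_frames = as.integer(movie_frames)),
            class = "sa_sim_geometry")
}

# Uniform points in a sphere of radius R (rejection sampling).
runif_sphere <- function(n, R) {
  out <- matrix(0, n, 3)
  need <- seq_len(n)
  while (length(need) > 0) {
    cand <- matrix(stats::runif(3 * length(need), -R, R), ncol = 3)
    ok <- rowSums(cand^2) <= R^2
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }
  out
}

# Specular reflection of radial overshoot about the sphere surface,
# repeated until all points are inside.
reflect_sphere <- function(pos, R) {
  repeat {
    r <- sqrt(rowSums(pos^2))
    out <- r > R
    if (!any(out)) return(pos)
    pos[out, ] <- pos[out, , drop = FALSE] * ((2 * R - r[out]) / r[out])
  }
}

# Euler-Maruyama propagation of one batch of particles through the
# observation geometry.  `state` indexes into D (per-state diffusion
# coefficient); if rate > 0 the particles switch between states 1 and 2
# as a symmetric Markov chain resolved on the subframe grid.
# Returns the observed detections (true positions, no localization
# error) as a data.frame(particle, state, frame, x, y) where `state` is
# the particle's state (initial state when switching).
propagate_batch <- function(state, D, rate, nsub, geom) {
  n_p <- length(state)
  dt <- geom$frame_interval
  R <- geom$radius
  n_pos <- floor(stats::rexp(n_p, geom$bleach_rate) / dt) + 1
  t0 <- sample.int(geom$movie_frames, n_p, replace = TRUE) - 1L
  maxF <- max(n_pos)

  pos <- runif_sphere(n_p, R)
  cur_state <- state
  p_switch <- if (rate > 0) 1 - exp(-rate * dt / nsub) else 0
  if (rate * dt / nsub > 0.5)
    stop("transition rate too fast for the subframe resolution; increase subframes")

  Xo <- vector("list", maxF)
  slab <- geom$focal_depth / 2
  record <- function(f) {
    alive <- which(n_pos >= f)
    inslab <- alive[abs(pos[alive, 3]) <= slab]
    if (length(inslab) > 0)
      Xo[[f]] <<- data.frame(particle = inslab, frame = f,
                             x = pos[inslab, 1], y = pos[inslab, 2])
    invisible(NULL)
  }
  record(1L)
  sub_sd_state <- sqrt(2 * D * dt / nsub)
  for (f in seq_len(maxF)[-1]) {
    alive <- which(n_pos >= f)
    if (length(alive) == 0) break
    for (s in seq_len(nsub)) {
      if (p_switch > 0) {
        flip <- stats::runif(length(alive)) < p_switch
        cur_state[alive[flip]] <- 3L - cur_state[alive[flip]]
      }
      sd_sub <- sub_sd_state[cur_state[alive]]
      step <- matrix(stats::rnorm(3 * length(alive)), ncol = 3) * sd_sub
      pos[alive, ] <- reflect_sphere(pos[alive, , drop = FALSE] + step, R)
    }
    record(f)
  }
  obs <- do.call(rbind, Xo[!vapply(Xo, is.null, logical(1))])
  if (is.null(obs)) return(NULL)
  obs$frame <- obs$frame + t0[obs$particle]
  obs$state <- state[obs$particle]
  obs[order(obs$particle, obs$frame), ]
}

# Count observation runs in a detections table (particle, frame
# sorted): total runs and runs with >= 2 detections.
count_runs <- function(obs) {
  if (is.null(obs) || nrow(obs) == 0) return(c(all = 0L, len2 = 0L))
  n <- nrow(obs)
  if (n == 1) return(c(all = 1L, len2 = 0L))
  consec <- obs$particle[-1] == obs$particle[-n] & diff(obs$frame) == 1L
  start <- c(TRUE, !consec)
  c(all = sum(start), len2 = sum(start[-n] & consec))
}

# Keep only the first n trajectories of a dataset (in id order).
truncate_dataset <- function(ds, n) {
  if (ds$n_trajectories <= n) return(ds)
  ds$positions <- ds$positions[ds$positions$trajectory <= n, , drop = FALSE]
  ds$index <- ds$index[ds$index$trajectory <= n, , drop = FALSE]
  ds$n_trajectories <- n
  ds$total_jumps <- sum(ds$index$L)
  ds
}

# Shared driver for the batch loop: draws particles, propagates them,
# injects localization error, and assembles the final dataset once the
# trajectory target is reached.
run_simulation <- function(model, geom, seed, rate, nsub, max_particles) {
  set.seed(seed)
  target <- geom$n_trajectories
  obs_all <- list()
  state_counts <- integer(length(model$D))
  n_traj <- 0L
  n_particles <- 0L
  n_runs_all <- 0L
  n_obs_positions <- 0L
  next_id <- 0L
  batch <- max(500L, min(target, 5000L))
  while (n_traj < target) {
    if (n_particles >= max_particles)
      stop("trajectory target not reached after ", n_particles,
           " particles; check bleach rate and geometry")
    state <- sample.int(length(model$D), batch, replace = TRUE,
                        prob = model$occupation)
    state_counts <- state_counts + tabulate(state, length(model$D))
    n_particles <- n_particles + batch
    obs <- propagate_batch(state, model$D, rate, nsub, geom)
    if (!is.null(obs)) {
      # localization error: iid per recorded position, per-state sigma
      sg <- model$sigma_loc[obs$state]
      obs$x <- obs$x + stats::rnorm(nrow(obs)) * sg
      obs$y <- obs$y + stats::rnorm(nrow(obs)) * sg
      obs$particle <- obs$particle + next_id
      obs_all[[length(obs_all) + 1L]] <- obs
      runs <- count_runs(obs)
      n_traj <- n_traj + runs[["len2"]]
      n_runs_all <- n_runs_all + runs[["all"]]
      n_obs_positions <- n_obs_positions + nrow(obs)
    }
    next_id <- next_id + batch
    # adapt batch size to the remaining deficit
    yield <- max(n_traj, 1L) / n_particles
    batch <- max(500L, min(50000L, ceiling(1.15 * (target - n_traj) / yield)))
  }
  obs <- do.call(rbind, obs_all)
  acq <- acquisition_params(
    frame_interval = geom$frame_interval, pixel_size = 1,
    focal_depth = geom$focal_depth, start_frame = 0L
  )
  ds <- trajectory_dataset(
    data.frame(trajectory = obs$particle, frame = obs$frame,
               x = obs$x, y = obs$y),
    acq, unit = "um"
  )
  ds <- truncate_dataset(ds, target)
  pstate <- obs$state[match(ds$index$source_id, obs$particle)]
  truth <- list(
    state = pstate,
    state_D = model$D[pstate],
    state_sigma_loc = model$sigma_loc[pstate],
    realized_occupations = state_counts / sum(state_counts),
    nominal_occupations = model$occupation,
    model = model,
    n_particles = n_particles
  )
  # mean observed transit length in frames, counting every focal-slab
  # transit (including single-detection ones, as raw tracking output would)
  list(dataset = ds, truth = truth,
       mean_transit_length = n_obs_positions / n_runs_all)
}

#' Simulate an sptPALM trajectory dataset
#'
#' Generates ground-truth trajectories under a discrete-state Brownian
#' mixture with the full observation geometry of a stroboscopic
#' sptPALM experiment: particles photoactivate uniformly inside a
#' reflecting sphere at random movie frames, diffuse by the
#' Euler-Maruyama scheme with specular reflection at the boundary,
#' photobleach with exponential lifetimes, and are recorded only on
#' frames whose (true) axial position lies in the focal slab.  Each
#' re-entry into the slab starts a new trajectory (gapless tracking),
#' single-detection transits are dropped, and iid Gaussian localization
#' error with the state's sigma_loc is added to every recorded
#' position.  Simulation proceeds until `geom$n_trajectories`
#' trajectories with at least one jump exist.
#'
#' State membership of each particle is a multinomial draw from the
#' model occupations, so the realized ("true") occupations returned
#' differ slightly from the nominal ones, exactly as in a real
#' photoactivation experiment.
#'
#' @param model An [sim_state_model()].
#' @param geom An [sim_geometry()].
#' @param seed Integer seed; identical inputs give byte-identical
#'   datasets.
#' @param subframes Euler-Maruyama substeps per frame interval (>= 1;
#'   default 10 so boundary reflections are resolved).
#' @param max_particles Safety cap on simulated particles.
#' @return list with `dataset` (an `sa_dataset`), `truth` (list:
#'   per-trajectory `state` labels and true parameters,
#'   `realized_occupations`, `nominal_occupations`, `n_particles`) and
#'   `mean_transit_length` (mean observed transit length in frames over
#'   all focal-slab transits, including single-detection ones).
#' @export
simulate_dataset <- function(model, geom, seed, subframes = 10L,
                             max_particles = 5e6) {
  stopifnot(inherits(model, "sa_sim_model"), inherits(geom, "sa_sim_geometry"))
  run_simulation(model, geom, seed, rate = 0, nsub = as.integer(subframes),
                 max_particles = max_particles)
}

#' Simulate trajectories with two-state switching
#'
#' As [simulate_dataset()], but particles switch between two diffusive
#' states as a symmetric continuous-time Markov chain (identical rates
#' in both directions), discretized on `subframes` sub-intervals per
#' frame; within a subframe the state is constant and displacement
#' follows the Euler-Maruyama scheme with the current diffusion
#' coefficient.
#'
#' @param D1,D2 Diffusion coefficients of the two states, um^2/s.
#' @param rate Transition rate constant, 1/s (`rate = 0` reduces to two
#'   fixed states at equal occupation).
#' @param geom An [sim_geometry()].
#' @param seed Integer seed.
#' @param sigma_loc Localization error (um), common to both states.
#' @param subframes Subframes per frame interval (default 100).
#' @param max_particles Safety cap on simulated particles.
#' @return As [simulate_dataset()]; `truth$state` is the state at
#'   photoactivation.
#' @export
simulate_transitions <- function(D1, D2, rate, geom, seed, sigma_loc = 0.035,
                                 subframes = 100L, max_particles = 5e6) {
  stopifnot(inherits(geom, "sa_sim_geometry"), rate >= 0)
  model <- sim_state_model(D = c(D1, D2), sigma_loc = sigma_loc,
                           occupation = c(0.5, 0.5))
  run_simulation(model, geom, seed, rate = rate,
                 nsub = as.integer(subframes), max_particles = max_particles)
}

#' Sample a fractional Brownian motion path with localization error
#'
#' Exact Gaussian-process sampling: the per-axis increments are drawn
#' jointly from the FBME increment covariance
#' ([fbme_increment_covariance()]) via its Cholesky factor, and
#' positions are their cumulative sums from the origin.  x and y are
#' independent.
#'
#' @param n_steps Number of increments (>= 1).
#' @param scale_mod Modified scaling coefficient, um^2/s.
#' @param hurst Hurst parameter in (0, 1).
#' @param loc_error_var Localization-error variance, um^2.
#' @param dt Frame interval, seconds.
#' @return list with `x`, `y` (positions, length `n_steps + 1`) and
#'   `dx`, `dy` (the increments).
#' @export
simulate_fbm_path <- function(n_steps, scale_mod, hurst, loc_error_var = 0,
                              dt = 0.00748) {
  stopifnot(n_steps >= 1)
  G <- fbme_increment_covariance(n_steps, scale_mod, hurst, loc_error_var, dt)
  Rch <- tryCatch(chol(G), error = function(e)
    stop("FBME increment covariance is not positive definite"))
  dx <- drop(crossprod(Rch, stats::rnorm(n_steps)))
  dy <- drop(crossprod(Rch, stats::rnorm(n_steps)))
  list(x = c(0, cumsum(dx)), y = c(0, cumsum(dy)), dx = dx, dy = dy)
}

#' Expected 2D radial displacement of a Brownian particle
#'
#' The mean length of a 2D Brownian displacement over time `t` is
#' \eqn{\sqrt{\pi D t}} (the mean of a Rayleigh variable with scale
#' \eqn{\sqrt{2Dt}}).  A Monte-Carlo estimate is available as a check.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param t Time interval, seconds.
#' @param method `"analytic"` (closed form) or `"mc"` (Monte Carlo).
#' @param n_samples Number of Monte-Carlo samples.
#' @return Expected displacement in um.
#' @export
expected_displacement_2d <- function(D, t, method = c("analytic", "mc"),
                                     n_samples = 1e6) {
  method <- match.arg(method)
  if (method == "analytic") return(sqrt(pi * D * t))
  s <- sqrt(2 * D * t)
  mean(sqrt(stats::rnorm(n_samples, sd = s)^2 +
            stats::rnorm(n_samples, sd = s)^2))
}
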