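#' Estimate localization error from sequential-jump covariance
#'
#' Measurement noise in a position feeds with opposite sign into the
#' two jumps that share it, so the lag-1 covariance of RBME jumps is
#' exactly `-sigma_loc^2` per axis.  The estimator pools the products
#' of sequential jump components over both axes and all trajectories
#' with at least two jumps, negates the mean, and clips at zero.
#'
#' @param ds An `sa_dataset`.
#' @return Estimated localization-error variance sigma_loc^2 (um^2).
#' @export
estimate_loc_error <- function(ds) {
  stopifnot(inherits(ds, "sa_dataset"))
  if (!any(ds$index$L >= 2))
    stop("localization-error estimation needs a trajectory with >= 2 jumps")
  j <- trajectory_jumps(ds)
  n <- nrow(j)
  within <- j$trajectory[-1] == j$trajectory[-n]
  prods <- c((j$dx[-1] * j$dx[-n])[within],
             (j$dy[-1] * j$dy[-n])[within])
  max(-mean(prods), 0)
}

#' Configuration of the Dirichlet-process mixture sampler
#'
#' @param alpha Concentration parameter of the Dirichlet process.
#' @param m0 Number of uniform auxiliary candidates drawn when a
#'   trajectory opens a new state; also the initial number of states.
#' @param nu Standard deviation of the Metropolis-Hastings proposal in
#'   phi units.
#' @param d_min,d_max Diffusion-coefficient range (um^2/s) mapped to the
#'   phi support at the dataset's frame interval and localization error.
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before summarizing.
#' @param seed Integer seed.
#' @return An object of class `dpmm_config`.
#' @export
dpmm_config <- function(alpha = 5, m0 = 20L, nu = 0.1,
                        d_min = 1e-2, d_max = 1e2,
                        n_iter = 2000L, burn_in = 500L, seed = 1L) {
  stopifnot(alpha > 0, m0 >= 1, nu > 0, d_min > 0, d_min < d_max,
            n_iter >= 1, burn_in >= 0, burn_in < n_iter)
  structure(list(alpha = alpha, m0 = as.integer(m0), nu = nu,
                 d_min = d_min, d_max = d_max,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "dpmm_config")
}

#' Dirichlet-process mixture Gibbs sampler
#'
#' Samples the posterior over the 1D state parameter
#' \eqn{\phi = \log[4(D\,\Delta t + \sigma_{loc}^2)]} under the
#' marginal gamma likelihood ([gamma_log_likelihood()]), using an
#' auxiliary-candidate Gibbs sweep: each trajectory either joins an
#' existing state — chosen with probability proportional to the number
#' of jumps already assigned times its likelihood — with probability
#' `(N-1)/(alpha+N-1)`, or opens a new state, drawn from `m0` uniform
#' candidates weighted by likelihood, with probability
#' `alpha/(alpha+N-1)`.  Empty states are removed each sweep and every
#' surviving state parameter receives a truncated-Gaussian
#' Metropolis-Hastings nudge whose acceptance ratio includes the
#' truncation-volume correction
#' \eqn{[\Phi((\phi_{max}-\phi)/\nu) - \Phi((\phi_{min}-\phi)/\nu)]}.
#' The standard accept-when-`u < r` Metropolis rule is used.  Traces
#' are deterministic given the seed.
#'
#' @param ds An `sa_dataset`.
#' @param cfg A [dpmm_config()].
#' @param loc_error_var Localization-error variance used to map the
#'   diffusion range onto the phi support; estimated from the data via
#'   [estimate_loc_error()] when `NULL`.
#' @return An object of class `dpmm_chain`: list with `trace`
#'   (data.frame iteration/phi/n_jumps), `accept_rate`, `z_final`,
#'   `loc_error_var`, `phi_min`, `phi_max`, `cfg`, `dt`,
#'   `total_jumps`.
#' @export
dpmm_gibbs <- function(ds, cfg = dpmm_config(), loc_error_var = NULL) {
  stopifnot(inherits(ds, "sa_dataset"), inherits(cfg, "dpmm_config"))
  dt <- ds$acquisition$frame_interval
  if (is.null(loc_error_var)) loc_error_var <- estimate_loc_error(ds)
  phi_min <- log(4 * (cfg$d_min * dt + loc_error_var))
  phi_max <- log(4 * (cfg$d_max * dt + loc_error_var))
  set.seed(cfg$seed)
  out <- dpmm_gibbs_core(ds$index$S, as.numeric(ds$index$L), cfg$alpha,
                         cfg$m0, cfg$nu, phi_min, phi_max, cfg$n_iter)
  structure(
    list(
      trace = data.frame(iteration = out$iteration, phi = out$phi,
                         n_jumps = out$n_jumps),
      accept_rate = out$accept_rate,
      z_final = out$z_final + 1L,
      loc_error_var = loc_error_var,
      phi_min = phi_min, phi_max = phi_max,
      cfg = cfg, dt = dt,
      total_jumps = ds$total_jumps
    ),
    class = "dpmm_chain"
  )
}

#' @export
print.dpmm_chain <- function(x, ...) {
  ks <- tapply(x$trace$phi, x$trace$iteration, length)
  cat(sprintf("DPMM chain: %d iterations (burn-in %d)\n",
              x$cfg$n_iter, x$cfg$burn_in))
  cat(sprintf("  states per iteration: median %g (range %d-%d)\n",
              stats::median(ks), min(ks), max(ks)))
  cat(sprintf("  MH acceptance rate: %.3f\n", x$accept_rate))
  cat(sprintf("  sigma_loc^2 used: %.3g um^2\n", x$loc_error_var))
  invisible(x)
}

#' Posterior occupation profile from a DPMM chain
#'
#' Builds the jump-count-weighted histogram of post-burn-in `phi`
#' samples, converts each sample to a diffusion coefficient via
#' \eqn{D = (e^{\phi}/4 - \sigma_{loc}^2)/\Delta t}, assigns it to the
#' nearest vertex of `d_grid` (log spacing), and normalizes.  Samples
#' whose implied `D` falls below the grid minimum (including those with
#' \eqn{e^{\phi}/4 < \sigma_{loc}^2}) are clamped to the smallest
#' vertex and counted in attribute `"n_clamped"`.
#'
#' @param chain A `dpmm_chain`.
#' @param d_grid Diffusion-coefficient axis for the histogram; defaults
#'   to [default_diffusion_axis()].
#' @return An `occupation_profile` over `d_grid` (uncorrected;
#'   apply [correct_occupations()] for defocalization).
#' @export
dpmm_posterior_profile <- function(chain, d_grid = default_diffusion_axis()) {
  stopifnot(inherits(chain, "dpmm_chain"))
  tr <- chain$trace[chain$trace$iteration > chain$cfg$burn_in, ]
  if (nrow(tr) == 0) stop("no post-burn-in samples in chain")
  Dsamp <- (exp(tr$phi) / 4 - chain$loc_error_var) / chain$dt
  n_clamped <- sum(Dsamp < d_grid[1])
  Dsamp <- pmax(Dsamp, d_grid[1])
  # nearest grid vertex in log space
  idx <- findInterval(log(Dsamp), log(d_grid) +
                        c(diff(log(d_grid)) / 2, Inf)) + 1L
  idx <- pmin(idx, length(d_grid))
  w <- numeric(length(d_grid))
  agg <- rowsum(tr$n_jumps, idx)
  w[as.integer(rownames(agg))] <- agg[, 1]
  out <- new_profile(data.frame(D = d_grid), w / sum(w), "RBME",
                     marginal = TRUE)
  attr(out, "n_clamped") <- n_clamped
  out
}
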