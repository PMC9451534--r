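#' Variational inference of the state-array posterior
#'
#' Runs the mean-field EM algorithm for the grid mixture: occupations
#' carry a symmetric Dirichlet prior with concentration `alpha` split
#' evenly over the K grid states, and each trajectory contributes to the
#' occupation pseudocounts in proportion to its number of jumps
#' (treating jumps, not trajectories, as the unit of evidence makes the
#' estimate robust to the short-trajectory bias of thin focal volumes).
#' The updates alternate
#' \deqn{n_k = \alpha/K + \sum_i L_i r_{ik}, \qquad
#'       r_{ik} = A_{ik} e^{\psi(n_k)} / \sum_j A_{ij} e^{\psi(n_j)}}
#' from the initialization \eqn{r^{(0)}_{ik} = A_{ik}/\sum_j A_{ij}},
#' where \eqn{\psi} is the digamma function, until the posterior mean
#' occupations change by less than `tol` (max norm) or `max_iter`
#' iterations.
#'
#' @param lik An `sa_likelihood` from [evaluate_grid()].
#' @param alpha Total Dirichlet concentration (default 1).  The state
#'   array approximates a Dirichlet process whose concentration stays
#'   O(1) as the grid grows, so the prior is split as `alpha/K` per
#'   vertex and kept small relative to the observed jumps.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the max change in E\[tau\];
#'   integrated occupation summaries typically stabilize two orders of
#'   magnitude before this strict per-vertex criterion is met.
#' @return An `sa_posterior`: list with `r` (N x K responsibilities),
#'   `n` (K pseudocounts), `grid`, `L`, `alpha`, `converged`,
#'   `iterations`.
#' @export
sa_infer <- function(lik, alpha = 1, max_iter = 250L, tol = 1e-6) {
  stopifnot(inherits(lik, "sa_likelihood"), max_iter >= 0, tol > 0)
  K <- lik$grid$K
  stopifnot(alpha > 0)
  if (any(!is.finite(lik$A)) || any(lik$A < 0))
    stop("likelihood matrix must be finite and nonnegative")
  fit <- sa_em_core(lik$A, as.numeric(lik$L), alpha / K,
                    as.integer(max_iter), tol)
  structure(
    list(r = fit$r, n = fit$n, grid = lik$grid, L = lik$L, alpha = alpha,
         converged = fit$converged, iterations = fit$iterations,
         delta_trace = fit$delta_trace),
    class = "sa_posterior"
  )
}

#' @export
print.sa_posterior <- function(x, ...) {
  cat(sprintf("State-array posterior: %d trajectories x %d states\n",
              nrow(x$r), x$grid$K))
  cat(sprintf("  converged: %s after %d iterations\n",
              x$converged, x$iterations))
  inv <- occupations(x)
  cat(sprintf("  occupation-weighted mean D: %.4g um^2/s\n",
              sum(inv$occupations * inv$states$D)))
  invisible(x)
}

new_profile <- function(states, occupations, motion, corrected = FALSE,
                        marginal = FALSE) {
  structure(
    list(states = states, occupations = as.numeric(occupations),
         motion = motion, corrected = corrected, marginal = marginal),
    class = "occupation_profile"
  )
}

#' Posterior mean occupations over the full grid
#'
#' @param post An `sa_posterior`.
#' @return An `occupation_profile` over all grid states
#'   (\eqn{E[\tau_k] = n_k / \sum_j n_j}).
#' @export
occupations <- function(post) {
  stopifnot(inherits(post, "sa_posterior"))
  new_profile(post$grid$states, post$n / sum(post$n), post$grid$motion)
}

#' Naive (initialization) state occupations
#'
#' The jump-count-weighted average of row-normalized likelihoods,
#' \deqn{\tau_{naive,k} = \sum_i L_i r^{(0)}_{ik} / \sum_j \sum_i L_i r^{(0)}_{ij},}
#' i.e. the state-array posterior occupations at the initial value of
#' the responsibilities, before any variational refinement.  Cheap
#' enough to evaluate per cell or per temporal block.
#'
#' @param lik An `sa_likelihood`.
#' @return An `occupation_profile` over the full grid.
#' @export
naive_occupations <- function(lik) {
  stopifnot(inherits(lik, "sa_likelihood"))
  r0 <- lik$A / rowSums(lik$A)
  w <- colSums(r0 * lik$L)
  new_profile(lik$grid$states, w / sum(w), lik$grid$motion)
}

#' Marginalize localization error out of an occupation profile
#'
#' Sums the occupations over the sigma_loc axis, leaving a profile over
#' the diffusion coefficient (RBME) or over scaling coefficient and
#' Hurst parameter (FBME).  Total mass is preserved exactly.
#'
#' @param profile An `occupation_profile` over a grid with a
#'   localization-error axis.
#' @return A marginal `occupation_profile`.
#' @export
marginalize_loc_error <- function(profile) {
  stopifnot(inherits(profile, "occupation_profile"))
  st <- profile$states
  if (!"sigma_loc" %in% names(st) || length(unique(st$sigma_loc)) == 1L) {
    if (!"sigma_loc" %in% names(st))
      warning("profile has no localization-error axis; returning unchanged")
    out <- profile
    out$states$sigma_loc <- NULL
    out$marginal <- TRUE
    return(out)
  }
  keep <- setdiff(names(st), "sigma_loc")
  agg <- stats::aggregate(profile$occupations, by = st[keep], FUN = sum)
  agg <- agg[do.call(order, agg[keep]), , drop = FALSE]
  new_profile(agg[keep], agg$x, profile$motion,
              corrected = profile$corrected, marginal = TRUE)
}

#' Integrated occupation over a diffusion-coefficient range
#'
#' Sums the occupations of grid states with `d_min <= D < d_max`
#' (half-open, so a set of ranges partitioning the axis partitions the
#' mass).
#'
#' @param profile An `occupation_profile`.
#' @param d_min,d_max Range limits in um^2/s, `0 <= d_min < d_max`.
#' @return The occupation fraction in the range.
#' @export
occupation_in_range <- function(profile, d_min, d_max) {
  stopifnot(inherits(profile, "occupation_profile"),
            d_min >= 0, d_min < d_max)
  D <- profile$states$D
  sel <- D >= d_min & D < d_max
  if (!any(sel)) {
    warning("no grid states in range [", d_min, ", ", d_max, ")")
    return(0)
  }
  sum(profile$occupations[sel])
}

#' Mean free diffusion coefficient
#'
#' Occupation-weighted mean of the diffusion coefficient over states at
#' or above `threshold`; the complementary mass below the threshold is
#' the immobile fraction.
#'
#' @param profile An `occupation_profile`.
#' @param threshold Mobility threshold in um^2/s (default 0.05).
#' @return Mean diffusion coefficient of the mobile mass, um^2/s.
#' @export
mean_free_diffusion <- function(profile, threshold = 0.05) {
  stopifnot(inherits(profile, "occupation_profile"))
  D <- profile$states$D
  sel <- D >= threshold
  w <- profile$occupations[sel]
  if (sum(w) <= 0) stop("no occupation mass at or above threshold ", threshold)
  sum(w * D[sel]) / sum(w)
}

#' Immobile fraction of an occupation profile
#'
#' Total occupation below `threshold` um^2/s.
#'
#' @inheritParams mean_free_diffusion
#' @return Fraction in \[0, 1\].
#' @export
immobile_fraction <- function(profile, threshold = 0.05) {
  stopifnot(inherits(profile, "occupation_profile"))
  sum(profile$occupations[profile$states$D < threshold])
}

#' Cumulative occupation over the diffusion axis
#'
#' @param profile A marginal `occupation_profile` over D.
#' @return data.frame with columns `D` and `cdf` (cumulative occupation
#'   at each grid vertex, in grid order).
#' @export
occupation_cdf <- function(profile) {
  stopifnot(inherits(profile, "occupation_profile"))
  ord <- order(profile$states$D)
  data.frame(D = profile$states$D[ord],
             cdf = cumsum(profile$occupations[ord]))
}

#' @export
print.occupation_profile <- function(x, ...) {
  cat(sprintf("Occupation profile (%s%s%s): %d states\n", x$motion,
              if (x$marginal) ", marginal" else "",
              if (x$corrected) ", defocalization-corrected" else "",
              length(x$occupations)))
  top <- order(x$occupations, decreasing = TRUE)[1:min(3, length(x$occupations))]
  for (k in top)
    cat(sprintf("  D=%.4g um^2/s: %.3f\n", x$states$D[k], x$occupations[k]))
  invisible(x)
}
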