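# Axial density profiles are lists: z (cell centers, um, symmetric about
# 0, regular spacing), f (cell-averaged density, um^-1), h (spacing).

# Fractional overlap of each grid cell [z - h/2, z + h/2] with the
# focal slab [-dz/2, dz/2]; a cell-averaged transmission function that
# keeps the midpoint quadrature second-order at the slab edges.
slab_coverage <- function(z, h, focal_depth) {
  lo <- pmax(z - h / 2, -focal_depth / 2)
  hi <- pmin(z + h / 2, focal_depth / 2)
  pmax(hi - lo, 0) / h
}

# Symmetric z grid for propagating a state with diffusion coefficient D:
# spacing about min(dz/50, sigma_z/8), extent dz/2 + 6 sigma_z
# sqrt(n_frames).  The spacing is snapped so the slab spans an odd whole
# number of cells: the slab edges then coincide with cell boundaries,
# the transmission function is exactly 0/1 per cell, and applying it is
# idempotent (a D = 0 profile is left untouched).
axial_grid <- function(D, dt, focal_depth, n_frames = 1) {
  sz <- sqrt(2 * D * dt)
  h0 <- if (sz > 0) min(focal_depth / 50, sz / 8) else focal_depth / 50
  m <- ceiling(focal_depth / h0)
  if (m %% 2 == 0) m <- m + 1
  h <- focal_depth / m
  zmax <- focal_depth / 2 + 6 * sz * sqrt(n_frames)
  M <- ceiling(zmax / h)
  list(z = h * (-M:M), h = h)
}

#' Uniform in-slab axial profile
#'
#' The initial condition of the defocalization propagator: unit mass
#' spread uniformly over the focal slab, discretized on a grid adequate
#' for diffusion coefficient `D`.
#'
#' @param D Diffusion coefficient the profile will be propagated with,
#'   um^2/s (sets the grid resolution/extent).
#' @param dt Frame interval, seconds.
#' @param focal_depth Slab depth, um.
#' @param n_frames Number of propagation steps the grid must support.
#' @return An axial profile: list with `z` (cell centers, um), `f`
#'   (density, um^-1) and `h` (spacing, um).
#' @export
slab_profile <- function(D, dt, focal_depth, n_frames = 1) {
  g <- axial_grid(D, dt, focal_depth, n_frames)
  cov <- slab_coverage(g$z, g$h, focal_depth)
  f <- cov / focal_depth
  f <- f / (sum(f) * g$h)   # unit mass exactly
  list(z = g$z, f = f, h = g$h)
}

#' One step of the defocalization propagator
#'
#' Convolves the axial density with the Brownian Green's function of
#' variance `2*D*dt`, then multiplies by the slab transmission function
#' (1 inside `[-focal_depth/2, focal_depth/2]`, 0 outside, with
#' cell-averaged edge handling).  Total mass can only decrease.
#'
#' @param profile An axial profile as returned by [slab_profile()].
#' @param D Diffusion coefficient, um^2/s.
#' @param dt Frame interval, seconds.
#' @param focal_depth Slab depth, um.
#' @return The propagated axial profile.
#' @export
diffuse_step <- function(profile, D, dt, focal_depth) {
  stopifnot(D >= 0, dt > 0, focal_depth > 0)
  z <- profile$z
  h <- profile$h
  f <- profile$f
  sz <- sqrt(2 * D * dt)
  if (sz > 0) {
    if (h > sz / 4)
      stop(sprintf(
        "axial grid too coarse for D=%g: spacing %g exceeds sigma_z/4 = %g; refine the grid",
        D, h, sz / 4))
    Kk <- ceiling(6 * sz / h)
    kern <- stats::dnorm(h * (-Kk:Kk), 0, sz) * h
    full <- stats::convolve(f, rev(kern), type = "open")
    f <- full[(Kk + 1):(Kk + length(z))]
  }
  f <- f * slab_coverage(z, h, focal_depth)
  list(z = z, f = pmax(f, 0), h = h)
}

#' Fraction of particles remaining in focus
#'
#' Probability that a Brownian particle, initially uniformly distributed
#' in the focal slab, is still inside the slab at every one of the next
#' `n_frames` frame intervals.  Computed by `n_frames` applications of
#' the convolution-transmission propagator [diffuse_step()] followed by
#' integration of the surviving density.  Monotonically decreasing in
#' `D` and in `n_frames`; depends on the parameters only through
#' `sqrt(2*D*dt)/focal_depth`.
#'
#' @param D Diffusion coefficient(s), um^2/s (vectorized).
#' @param dt Frame interval, seconds.
#' @param focal_depth Slab depth, um.
#' @param n_frames Number of frame intervals (default 1, the value used
#'   for occupation corrections).
#' @return Fraction(s) in `[0, 1]`.
#' @export
fraction_in_focus <- function(D, dt, focal_depth, n_frames = 1) {
  stopifnot(focal_depth > 0, dt > 0, n_frames >= 1)
  vapply(D, function(d) {
    if (d <= 0) return(1)
    p <- slab_profile(d, dt, focal_depth, n_frames)
    for (i in seq_len(n_frames)) p <- diffuse_step(p, d, dt, focal_depth)
    min(sum(p$f) * p$h, 1)
  }, numeric(1))
}

#' Correct an occupation profile for defocalization bias
#'
#' Fast states defocalize quickly and are under-sampled in the observed
#' jumps; dividing each state's occupation by its one-frame in-focus
#' probability and renormalizing,
#' \deqn{\tau_k' = (\tau_k / \eta_k) / \sum_j (\tau_j / \eta_j),}
#' converts jump-weighted occupations into estimates of the underlying
#' population fractions.  For FBME profiles the scaling coefficient is
#' used as the effective one-frame diffusion coefficient, since the
#' first increment of FBME is Gaussian with variance `2*scale_mod*dt`
#' regardless of the Hurst parameter (an approximation for later
#' frames, exact for the one-step correction applied here).
#'
#' @param profile An `occupation_profile` (not yet corrected).
#' @param dt Frame interval, seconds.
#' @param focal_depth Slab depth, um.
#' @param n_frames Number of frame intervals for the in-focus
#'   probability (default 1).
#' @return The corrected `occupation_profile`, with the per-state
#'   in-focus fractions in attribute `"eta"`.
#' @export
correct_occupations <- function(profile, dt, focal_depth, n_frames = 1) {
  stopifnot(inherits(profile, "occupation_profile"))
  if (isTRUE(profile$corrected))
    stop("profile is already defocalization-corrected")
  D <- profile$states$D
  uD <- unique(D)
  eta_u <- fraction_in_focus(uD, dt, focal_depth, n_frames)
  eta <- eta_u[match(D, uD)]
  if (any(eta <= 0))
    stop("in-focus fraction is numerically zero at D = ",
         D[which(eta <= 0)[1]], " um^2/s")
  w <- profile$occupations / eta
  out <- new_profile(profile$states, w / sum(w), profile$motion,
                     corrected = TRUE, marginal = profile$marginal)
  attr(out, "eta") <- eta
  out
}
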