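#' Parameter grid for state-array inference
#'
#' Defines the fixed grid of candidate states over which occupations are
#' inferred.  For regular Brownian motion with localization error (RBME)
#' the grid is 2D: diffusion coefficients log-spaced on
#' \eqn{[10^{-2}, 10^2]} um^2/s crossed with localization errors
#' (sigma_loc, um) linearly spaced on \eqn{[0, 0.06]}.  For fractional
#' Brownian motion with localization error (FBME) the grid is 3D over
#' the modified scaling coefficient, the Hurst parameter and the
#' localization error.
#'
#' @param diffusion_values Nondecreasing diffusion coefficients
#'   (um^2/s); for FBME these are modified scaling coefficients
#'   \eqn{\bar S} (um^2/s).  Duplicate vertices are allowed (posterior
#'   mass splits among them).
#' @param loc_error_values Nondecreasing localization errors
#'   sigma_loc (um, standard deviation per axis).
#' @param hurst_values Optional nondecreasing Hurst parameters in
#'   (0, 1); supplying them selects the FBME motion model.
#' @return An object of class `sa_grid` with a `states` data.frame
#'   enumerating all vertices (diffusion axis varying fastest) and the
#'   axis vectors.
#' @examples
#' g <- parameter_grid()
#' g$K
#' @export
parameter_grid <- function(diffusion_values = default_diffusion_axis(),
                           loc_error_values = default_loc_error_axis(),
                           hurst_values = NULL) {
  check_axis <- function(v, name, positive_only = FALSE) {
    if (!is.numeric(v) || length(v) < 1 || anyNA(v))
      stop(name, " must be a numeric vector without NA")
    if (length(v) > 1 && any(diff(v) < 0))
      stop(name, " must be nondecreasing")
    if (any(v < 0)) stop(name, " must be nonnegative")
  }
  check_axis(diffusion_values, "diffusion_values")
  check_axis(loc_error_values, "loc_error_values")
  motion <- "RBME"
  if (!is.null(hurst_values)) {
    check_axis(hurst_values, "hurst_values")
    if (any(hurst_values <= 0) || any(hurst_values >= 1))
      stop("hurst_values must lie strictly inside (0, 1)")
    motion <- "FBME"
  }

  if (motion == "RBME") {
    states <- expand.grid(
      D = diffusion_values, sigma_loc = loc_error_values,
      KEEP.OUT.ATTRS = FALSE
    )
  } else {
    states <- expand.grid(
      D = diffusion_values, hurst = hurst_values,
      sigma_loc = loc_error_values, KEEP.OUT.ATTRS = FALSE
    )
  }

  structure(
    list(
      motion = motion,
      diffusion_values = diffusion_values,
      loc_error_values = loc_error_values,
      hurst_values = hurst_values,
      states = states,
      K = nrow(states)
    ),
    class = "sa_grid"
  )
}

#' Default diffusion-coefficient axis
#'
#' @param n Number of grid points.
#' @param d_min,d_max Range in um^2/s.
#' @return Log-spaced vector of diffusion coefficients.
#' @export
default_diffusion_axis <- function(n = 101L, d_min = 1e-2, d_max = 1e2) {
  10^seq(log10(d_min), log10(d_max), length.out = n)
}

#' Default localization-error axis
#'
#' @param n Number of grid points.
#' @param s_max Maximum sigma_loc in um.
#' @return Linearly spaced vector of localization errors (um).
#' @export
default_loc_error_axis <- function(n = 36L, s_max = 0.06) {
  seq(0, s_max, length.out = n)
}

#' Default FBME grid
#'
#' 3D grid over the modified scaling coefficient (log-spaced), the Hurst
#' parameter (linear on (0, 1)) and the localization error.
#'
#' @param n_scale,n_hurst,n_sigma Axis lengths.
#' @return An `sa_grid` with `motion == "FBME"`.
#' @export
fbme_grid <- function(n_scale = 31L, n_hurst = 19L, n_sigma = 13L) {
  parameter_grid(
    diffusion_values = default_diffusion_axis(n_scale),
    loc_error_values = default_loc_error_axis(n_sigma),
    hurst_values = seq(0.05, 0.95, length.out = n_hurst)
  )
}

#' @export
print.sa_grid <- function(x, ...) {
  cat(sprintf("%s parameter grid: %d states\n", x$motion, x$K))
  cat(sprintf("  D: %d points on [%g, %g] um^2/s\n",
              length(x$diffusion_values), min(x$diffusion_values),
              max(x$diffusion_values)))
  cat(sprintf("  sigma_loc: %d points on [%g, %g] um\n",
              length(x$loc_error_values), min(x$loc_error_values),
              max(x$loc_error_values)))
  if (!is.null(x$hurst_values))
    cat(sprintf("  Hurst: %d points on [%g, %g]\n",
                length(x$hurst_values), min(x$hurst_values),
                max(x$hurst_values)))
  invisible(x)
}
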