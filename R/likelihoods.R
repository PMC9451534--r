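#' Covariance matrix of RBME jumps
#'
#' For a Brownian particle with diffusion coefficient `D` observed at
#' frame interval `dt` with iid Gaussian localization error of variance
#' `loc_error_var` per axis, the per-axis jumps form a mean-zero
#' Gaussian vector with tridiagonal covariance
#' \deqn{\Gamma_{ii} = 2(D\,dt + \sigma_{loc}^2),\quad
#'       \Gamma_{ij} = -\sigma_{loc}^2 \ (|i-j|=1),\quad 0\ \mathrm{else.}}
#' The negative lag-1 term is the echo of each position's measurement
#' error in the two jumps that share it; it vanishes only when
#' `loc_error_var = 0`, in which case jumps are independent (Markov).
#'
#' @param L Number of jumps (matrix dimension), >= 1.
#' @param D Diffusion coefficient, um^2/s.
#' @param loc_error_var Localization-error variance sigma_loc^2, um^2.
#' @param dt Frame interval, seconds.
#' @return `L` x `L` symmetric matrix.
#' @export
rbme_covariance <- function(L, D, loc_error_var, dt) {
  stopifnot(L >= 1, L == as.integer(L), dt > 0, D >= 0, loc_error_var >= 0)
  G <- diag(2 * (D * dt + loc_error_var), nrow = L)
  if (L > 1) {
    off <- cbind(1:(L - 1), 2:L)
    G[off] <- -loc_error_var
    G[off[, 2:1, drop = FALSE]] <- -loc_error_var
  }
  G
}

# Eigenvalues of the L x L second-difference matrix tridiag(-1, 2, -1);
# the RBME covariance shares its eigenvectors (discrete sine transform),
# with eigenvalues 2*D*dt + sigma2 * lambda_j.
tridiag_eigenvalues <- function(L) 2 - 2 * cos(seq_len(L) * pi / (L + 1))

# Orthonormal DST eigenvector matrix of tridiag(-1, 2, -1).
dst_matrix <- function(L) {
  j <- seq_len(L)
  sqrt(2 / (L + 1)) * sin(outer(j, j) * pi / (L + 1))
}

#' Log-likelihood of a trajectory under RBME
#'
#' Evaluates the exact log density of the observed x- and y-jump
#' vectors under regular Brownian motion with localization error: two
#' independent `L`-dimensional Gaussians sharing the tridiagonal
#' covariance of [rbme_covariance()].  The quadratic forms are computed
#' through the closed-form eigendecomposition of the tridiagonal matrix,
#' which is exact and O(L^2).
#'
#' @param dx,dy Jump vectors along x and y (um), equal length `L >= 1`.
#' @param D Diffusion coefficient, um^2/s.
#' @param loc_error_var Localization-error variance, um^2.
#' @param dt Frame interval, seconds.
#' @return Log density (a single number).
#' @export
rbme_log_likelihood <- function(dx, dy, D, loc_error_var, dt) {
  L <- length(dx)
  stopifnot(L >= 1, length(dy) == L, dt > 0)
  lam <- tridiag_eigenvalues(L)
  d <- 2 * D * dt + loc_error_var * lam
  if (any(d <= 0))
    stop(sprintf("singular RBME covariance at D=%g, sigma_loc^2=%g",
                 D, loc_error_var))
  V <- dst_matrix(L)
  ux <- drop(crossprod(V, dx))
  uy <- drop(crossprod(V, dy))
  -0.5 * sum((ux^2 + uy^2) / d) - L * log(2 * pi) - sum(log(d))
}

#' Marginal gamma log-likelihood of a trajectory
#'
#' Neglecting the off-diagonal (localization-error) terms of the RBME
#' covariance, the likelihood of a trajectory depends on its data only
#' through the sum of squared 2D jumps `S` and the jump count `L`, and
#' on the parameters only through
#' \eqn{\phi = \log[4(D\,dt + \sigma_{loc}^2)]}:
#' \deqn{\log p(X \mid \phi) = -S e^{-\phi} - L\phi + \mathrm{const.}}
#' This is the 1D working likelihood of the Dirichlet-process sampler.
#'
#' @param S Sum of squared 2D jumps, um^2 (>= 0).
#' @param L Number of jumps (>= 1).
#' @param phi Log of 4(D*dt + sigma_loc^2).  May be a vector.
#' @return Log density up to an additive constant; vectorized over `phi`.
#' @export
gamma_log_likelihood <- function(S, L, phi) {
  stopifnot(S >= 0, L >= 1)
  -S * exp(-phi) - L * phi
}

#' Covariance matrix of FBME increments
#'
#' Increment covariance of fractional Brownian motion with Hurst
#' parameter `H`, observed at frame interval `dt` with localization
#' error.  Parameterized by the modified scaling coefficient
#' \eqn{\bar S = S\,dt^{2H-1}} (um^2/s), chosen so that the jump
#' variance equals \eqn{2\bar S\,dt + 2\sigma_{loc}^2} for every `H`:
#' \deqn{\Gamma_{ij} = \bar S\,dt\,(|i-j+1|^{2H} + |i-j-1|^{2H}
#'   - 2|i-j|^{2H}) + 2\sigma_{loc}^2 I_{i=j} - \sigma_{loc}^2 I_{|i-j|=1}.}
#' At `H = 0.5` this reduces exactly to [rbme_covariance()] with
#' `D` equal to `scale_mod`.
#'
#' @param L Number of jumps.
#' @param scale_mod Modified scaling coefficient (um^2/s).
#' @param hurst Hurst parameter in (0, 1).
#' @param loc_error_var Localization-error variance, um^2.
#' @param dt Frame interval, seconds.
#' @return `L` x `L` symmetric matrix.
#' @export
fbme_increment_covariance <- function(L, scale_mod, hurst, loc_error_var, dt) {
  stopifnot(L >= 1, L == as.integer(L), hurst > 0, hurst < 1,
            scale_mod >= 0, loc_error_var >= 0, dt > 0)
  dlag <- abs(outer(seq_len(L), seq_len(L), "-"))
  H2 <- 2 * hurst
  fbm <- abs(dlag + 1)^H2 + abs(dlag - 1)^H2 - 2 * dlag^H2
  G <- scale_mod * dt * fbm
  G <- G + diag(2 * loc_error_var, nrow = L)
  if (L > 1) {
    off <- abs(dlag) == 1
    G[off] <- G[off] - loc_error_var
  }
  G
}

#' Log-likelihood of a trajectory under FBME
#'
#' Generic Gaussian evaluation (Cholesky) of the FBME increment model
#' on the x- and y-jump vectors.
#'
#' @inheritParams rbme_log_likelihood
#' @param scale_mod Modified scaling coefficient (um^2/s).
#' @param hurst Hurst parameter in (0, 1).
#' @return Log density.
#' @export
fbme_log_likelihood <- function(dx, dy, scale_mod, hurst, loc_error_var, dt) {
  L <- length(dx)
  stopifnot(L >= 1, length(dy) == L)
  G <- fbme_increment_covariance(L, scale_mod, hurst, loc_error_var, dt)
  R <- tryCatch(chol(G), error = function(e)
    stop(sprintf("non-positive-definite FBME covariance at S=%g, H=%g, sigma_loc^2=%g",
                 scale_mod, hurst, loc_error_var)))
  zx <- backsolve(R, dx, transpose = TRUE)
  zy <- backsolve(R, dy, transpose = TRUE)
  -0.5 * sum(zx^2 + zy^2) - L * log(2 * pi) - 2 * sum(log(diag(R)))
}

# Split the dataset's jumps into per-L matrices:
# list of (L, rows = trajectory indices, X, Y) with X, Y of dim n_L x L.
jump_groups <- function(ds) {
  j <- trajectory_jumps(ds)
  Lvec <- ds$index$L
  lapply(sort(unique(Lvec)), function(L) {
    rows <- which(Lvec == L)
    sel <- j$trajectory %in% rows
    list(
      L = L,
      rows = rows,
      X = matrix(j$dx[sel], ncol = L, byrow = TRUE),
      Y = matrix(j$dy[sel], ncol = L, byrow = TRUE)
    )
  })
}

#' Evaluate the trajectory-by-state likelihood matrix
#'
#' Fills the N x K matrix \eqn{A_{ik} = p(X_i \mid \theta_k)} of
#' per-trajectory likelihoods over all grid states.  Likelihoods are
#' computed in log space; each row is shifted by its maximum before
#' exponentiation and (by default) normalized to sum to 1, which cancels
#' in the downstream responsibility updates but keeps the matrix
#' numerically well-scaled.  Grid vertices with a singular covariance
#' (only possible when both `D = 0` and `sigma_loc = 0` appear on a
#' custom grid) receive zero likelihood and are reported in the
#' `degenerate_states` attribute rather than aborting the run.
#'
#' For RBME the evaluation groups trajectories by jump count and uses
#' the discrete-sine-transform eigendecomposition of the tridiagonal
#' covariance, so the whole matrix is a handful of BLAS calls.  FBME
#' grids fall back to per-vertex Cholesky factorizations.
#'
#' @param ds An `sa_dataset`.
#' @param grid An `sa_grid`.
#' @param normalize Normalize each row to sum to 1 (default TRUE).
#' @return An object of class `sa_likelihood`: list with `A` (N x K),
#'   `L` (jump counts), `grid`, `row_norm`.
#' @export
evaluate_grid <- function(ds, grid, normalize = TRUE) {
  stopifnot(inherits(ds, "sa_dataset"), inherits(grid, "sa_grid"))
  if (any(ds$index$L < 1)) stop("all trajectories must have at least one jump")
  N <- ds$n_trajectories
  K <- grid$K
  dt <- ds$acquisition$frame_interval
  LL <- matrix(0, N, K)
  groups <- jump_groups(ds)

  if (grid$motion == "RBME") {
    Dk <- grid$states$D
    s2k <- grid$states$sigma_loc^2
    for (g in groups) {
      L <- g$L
      lam <- tridiag_eigenvalues(L)
      V <- dst_matrix(L)
      SQ <- (g$X %*% V)^2 + (g$Y %*% V)^2          # n_L x L
      dmat <- outer(lam, s2k) + rep(2 * dt * Dk, each = L)  # L x K eigenvalues
      bad <- dmat <= 0
      if (any(bad)) dmat[bad] <- 1            # placeholder; columns zeroed below
      block <- -0.5 * SQ %*% (1 / dmat)
      block <- block - rep(colSums(log(dmat)) + L * log(2 * pi), each = nrow(SQ))
      if (any(bad)) block[, colSums(bad) > 0] <- -Inf
      LL[g$rows, ] <- block
    }
    degenerate <- which(Dk == 0 & s2k == 0)
  } else {
    st <- grid$states
    degenerate <- integer(0)
    for (g in groups) {
      L <- g$L
      block <- matrix(-Inf, length(g$rows), K)
      for (k in seq_len(K)) {
        G <- fbme_increment_covariance(L, st$D[k], st$hurst[k],
                                       st$sigma_loc[k]^2, dt)
        R <- tryCatch(chol(G), error = function(e) NULL)
        if (is.null(R)) {
          degenerate <- union(degenerate, k)
          next
        }
        ZX <- backsolve(R, t(g$X), transpose = TRUE)
        ZY <- backsolve(R, t(g$Y), transpose = TRUE)
        block[, k] <- -0.5 * (colSums(ZX^2) + colSums(ZY^2)) -
          L * log(2 * pi) - 2 * sum(log(diag(R)))
      }
      LL[g$rows, ] <- block
    }
  }

  # per-row max shift, then exponentiate
  mx <- LL[cbind(seq_len(N), max.col(LL, ties.method = "first"))]
  if (any(!is.finite(mx)))
    stop("trajectory ", which(!is.finite(mx))[1],
         " has zero likelihood under every grid state")
  A <- exp(LL - mx)
  if (normalize) A <- A / rowSums(A)

  structure(
    list(A = A, L = ds$index$L, grid = grid, row_norm = normalize,
         degenerate_states = degenerate),
    class = "sa_likelihood"
  )
}
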