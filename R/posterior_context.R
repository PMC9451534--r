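#' Per-trajectory posterior distributions over diffusion coefficient
#'
#' The state array infers an individual posterior for every trajectory
#' (the responsibility rows); this marginalizes each row over the
#' localization-error axis, yielding an N x n_D matrix whose rows sum
#' to 1.
#'
#' @param post An `sa_posterior`.
#' @return Matrix (trajectories x diffusion grid points) with the D
#'   axis in attribute `"D"`.
#' @export
trajectory_posteriors <- function(post) {
  stopifnot(inherits(post, "sa_posterior"))
  D <- post$grid$states$D
  uD <- sort(unique(D))
  idx <- match(D, uD)
  out <- matrix(0, nrow(post$r), length(uD))
  for (k in seq_along(D))
    out[, idx[k]] <- out[, idx[k]] + post$r[, k]
  attr(out, "D") <- uD
  out
}

#' Named diffusion-coefficient ranges
#'
#' @param ... Named numeric vectors `c(min, max)` in um^2/s; ranges are
#'   half-open `[min, max)` and must be disjoint.
#' @return A named list of ranges (class `diffusion_ranges`).
#' @export
diffusion_ranges <- function(...) {
  rg <- list(...)
  stopifnot(length(rg) >= 1, !is.null(names(rg)), all(nzchar(names(rg))))
  for (r in rg) stopifnot(length(r) == 2, r[1] >= 0, r[1] < r[2])
  ord <- order(vapply(rg, `[`, numeric(1), 1))
  srt <- rg[ord]
  for (i in seq_along(srt)[-1])
    if (srt[[i]][1] < srt[[i - 1]][2])
      stop("diffusion ranges overlap: ", names(srt)[i - 1], " and ",
           names(srt)[i])
  structure(rg, class = "diffusion_ranges")
}

#' Spatial occupation map from per-trajectory posteriors
#'
#' Each trajectory contributes, at its first observed position, a
#' weight equal to its posterior mass in each diffusion range; a
#' Gaussian kernel density estimate (exact pairwise sums) is evaluated
#' per range on a regular spatial grid, and the per-range densities are
#' normalized pixelwise to fractional occupations wherever the summed
#' density exceeds `floor_frac` times its maximum.
#'
#' @param ds The `sa_dataset` the posterior was computed from.
#' @param post The matching `sa_posterior`.
#' @param ranges A [diffusion_ranges()] object.
#' @param bandwidth Gaussian kernel bandwidth, um (default 0.1).
#' @param cell Grid cell size, um.
#' @param anchor `"first"` (first observed position) or `"mean"`.
#' @param floor_frac Pixels with summed density below `floor_frac *
#'   max` are masked (NA) in the normalized maps.
#' @return list with `x`, `y` (grid axes), `density` (list of
#'   matrices per range) and `fraction` (pixelwise normalized
#'   fractions, NA where masked).
#' @export
spatial_occupation_map <- function(ds, post, ranges, bandwidth = 0.1,
                                   cell = 0.1, anchor = c("first", "mean"),
                                   floor_frac = 1e-3) {
  stopifnot(inherits(ds, "sa_dataset"), inherits(post, "sa_posterior"),
            inherits(ranges, "diffusion_ranges"), bandwidth > 0, cell > 0)
  anchor <- match.arg(anchor)
  if (nrow(post$r) != ds$n_trajectories)
    stop("posterior and dataset have different trajectory counts")
  tp <- trajectory_posteriors(post)
  Daxis <- attr(tp, "D")
  if (anchor == "first") {
    ax <- ds$index$x0
    ay <- ds$index$y0
  } else {
    ax <- as.numeric(tapply(ds$positions$x, ds$positions$trajectory, mean))
    ay <- as.numeric(tapply(ds$positions$y, ds$positions$trajectory, mean))
  }
  gx <- seq(min(ax) - 3 * bandwidth, max(ax) + 3 * bandwidth, by = cell)
  gy <- seq(min(ay) - 3 * bandwidth, max(ay) + 3 * bandwidth, by = cell)

  kde <- function(w) {
    # exact weighted Gaussian KDE on the grid (separable kernel)
    KX <- exp(-outer(gx, ax, "-")^2 / (2 * bandwidth^2))
    KY <- exp(-outer(gy, ay, "-")^2 / (2 * bandwidth^2))
    (KX %*% (w * t(KY))) / (2 * pi * bandwidth^2)
  }

  density <- lapply(ranges, function(r) {
    w <- rowSums(tp[, Daxis >= r[1] & Daxis < r[2], drop = FALSE])
    if (all(w == 0)) warning("range has zero posterior weight everywhere")
    kde(w)
  })
  total <- Reduce(`+`, density)
  mask <- total < floor_frac * max(total)
  fraction <- lapply(density, function(d) {
    f <- d / total
    f[mask] <- NA_real_
    f
  })
  list(x = gx, y = gy, density = density, fraction = fraction)
}

#' Naive occupation profiles over temporal blocks
#'
#' Assigns trajectories to blocks of `block` frames by their starting
#' frame (half-open `[b*block, (b+1)*block)`) and computes the naive
#' occupation estimate within each block, tracking how the dynamic
#' profile and localization density evolve over an acquisition.
#'
#' @param ds An `sa_dataset`.
#' @param grid An `sa_grid`.
#' @param block Block length in frames (default 100).
#' @return data.frame with one row per nonempty block: `block`,
#'   `start_frame`, `n_trajectories`, `n_localizations`, and the
#'   marginal naive occupation profiles in list-column `profile`.
#' @export
temporal_naive_profile <- function(ds, grid, block = 100L) {
  stopifnot(inherits(ds, "sa_dataset"), inherits(grid, "sa_grid"), block >= 1)
  lik <- evaluate_grid(ds, grid)
  bi <- ds$index$start_frame %/% block
  nloc <- rowsum(rep(1L, nrow(ds$positions)),
                 ds$positions$frame %/% block)
  blocks <- sort(unique(bi))
  profiles <- lapply(blocks, function(b) {
    rows <- which(bi == b)
    sub <- structure(
      list(A = lik$A[rows, , drop = FALSE], L = lik$L[rows],
           grid = grid, row_norm = lik$row_norm),
      class = "sa_likelihood"
    )
    marginalize_loc_error(naive_occupations(sub))
  })
  out <- data.frame(
    block = blocks,
    start_frame = blocks * block,
    n_trajectories = as.integer(table(factor(bi, levels = blocks))),
    n_localizations = as.integer(nloc[match(as.character(blocks),
                                            rownames(nloc))])
  )
  out$n_localizations[is.na(out$n_localizations)] <- 0L
  out$profile <- profiles
  out
}
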