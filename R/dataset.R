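#' Build a trajectory dataset from a table of detections
#'
#' Converts a raw table of linked detections (one row per localization)
#' into the container used by all inference routines.  Positions are
#' converted to micrometers, detections before `acquisition$start_frame`
#' are dropped, trajectories with frame gaps are split at each gap (the
#' likelihood models assume strictly consecutive frames), and
#' single-detection trajectories (zero jumps) are excluded from the
#' dataset but counted in the `n_singletons` field.
#'
#' @param df A data.frame with columns `trajectory`, `frame`, `x`, `y`.
#' @param acquisition An [acquisition_params()] object.
#' @param unit Either `"um"` (positions already in micrometers) or
#'   `"pixels"` (positions multiplied by `acquisition$pixel_size`).
#'
#' @return An object of class `sa_dataset` with elements
#'   \describe{
#'     \item{positions}{data.frame `trajectory`, `frame`, `x`, `y` (um),
#'       sorted by trajectory then frame; trajectory ids are re-indexed
#'       1..N after splitting, with the original id in `source_id`.}
#'     \item{index}{per-trajectory summary: number of jumps `L`, sum of
#'       squared 2D jump lengths `S` (um^2), first frame and first
#'       position.}
#'     \item{acquisition}{the acquisition metadata.}
#'     \item{n_trajectories, total_jumps, n_singletons}{counts.}
#'   }
#' @export
trajectory_dataset <- function(df, acquisition, unit = c("um", "pixels")) {
  unit <- match.arg(unit)
  stopifnot(inherits(acquisition, "sa_acquisition"))
  required <- c("trajectory", "frame", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("trajectory table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0)
    stop("empty trajectory table: no detections")
  for (cc in c("frame", "x", "y"))
    if (!is.numeric(df[[cc]]))
      stop("column '", cc, "' is not numeric")

  scale <- if (unit == "pixels") acquisition$pixel_size else 1
  df <- data.frame(
    trajectory = df$trajectory,
    frame = as.integer(df$frame),
    x = as.numeric(df$x) * scale,
    y = as.numeric(df$y) * scale
  )

  df <- df[df$frame >= acquisition$start_frame, , drop = FALSE]
  if (nrow(df) == 0)
    stop("empty trajectory table after start_frame filtering")

  df <- df[order(df$trajectory, df$frame), , drop = FALSE]

  # split at frame gaps: a new segment starts whenever the trajectory id
  # changes or the frame does not advance by exactly 1
  n <- nrow(df)
  same_traj <- c(FALSE, df$trajectory[-1] == df$trajectory[-n])
  consecutive <- c(FALSE, diff(df$frame) == 1L) & same_traj
  seg <- cumsum(!consecutive)

  seg_len <- tabulate(seg)
  keep_seg <- which(seg_len >= 2L)
  n_singletons <- sum(seg_len == 1L)
  if (length(keep_seg) == 0)
    stop("no trajectories with at least one jump after filtering/splitting")

  keep <- seg %in% keep_seg
  df <- df[keep, , drop = FALSE]
  seg <- seg[keep]
  new_id <- match(seg, unique(seg))

  positions <- data.frame(
    trajectory = new_id,
    frame = df$frame,
    x = df$x,
    y = df$y,
    source_id = df$trajectory
  )

  np <- nrow(positions)
  dx <- positions$x[-1] - positions$x[-np]
  dy <- positions$y[-1] - positions$y[-np]
  within <- positions$trajectory[-1] == positions$trajectory[-np]
  jump_traj <- positions$trajectory[-np][within]
  dx <- dx[within]
  dy <- dy[within]

  L <- tabulate(jump_traj)
  S <- as.numeric(rowsum(dx^2 + dy^2, jump_traj))
  first <- !duplicated(positions$trajectory)

  index <- data.frame(
    trajectory = positions$trajectory[first],
    source_id = positions$source_id[first],
    L = L,
    S = S,
    start_frame = positions$frame[first],
    x0 = positions$x[first],
    y0 = positions$y[first]
  )

  structure(
    list(
      positions = positions[, c("trajectory", "frame", "x", "y")],
      index = index,
      acquisition = acquisition,
      n_trajectories = nrow(index),
      total_jumps = sum(L),
      n_singletons = n_singletons
    ),
    class = "sa_dataset"
  )
}

#' Per-jump table of a trajectory dataset
#'
#' Returns one row per jump (displacement between consecutive frames)
#' with the trajectory it belongs to.
#'
#' @param ds An `sa_dataset`.
#' @return data.frame with columns `trajectory`, `dx`, `dy` (um).
#' @export
trajectory_jumps <- function(ds) {
  stopifnot(inherits(ds, "sa_dataset"))
  p <- ds$positions
  np <- nrow(p)
  within <- p$trajectory[-1] == p$trajectory[-np]
  data.frame(
    trajectory = p$trajectory[-np][within],
    dx = (p$x[-1] - p$x[-np])[within],
    dy = (p$y[-1] - p$y[-np])[within]
  )
}

#' Summary statistics of a trajectory dataset
#'
#' @param ds An `sa_dataset`.
#' @return A list with `n_trajectories`, `total_jumps`, `mean_length`
#'   (mean number of positions per trajectory, frames) and
#'   `mean_jump` (mean 2D jump length, um).
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "sa_dataset"))
  if (ds$n_trajectories < 1) stop("empty dataset")
  j <- trajectory_jumps(ds)
  list(
    n_trajectories = ds$n_trajectories,
    total_jumps = ds$total_jumps,
    mean_length = mean(ds$index$L + 1),
    mean_jump = mean(sqrt(j$dx^2 + j$dy^2))
  )
}

#' @export
print.sa_dataset <- function(x, ...) {
  cat("Trajectory dataset\n")
  cat(sprintf("  trajectories: %d (singletons excluded: %d)\n",
              x$n_trajectories, x$n_singletons))
  cat(sprintf("  total jumps:  %d\n", x$total_jumps))
  cat(sprintf("  mean length:  %.2f frames\n", mean(x$index$L + 1)))
  cat(sprintf("  frame interval %g s, focal depth %g um\n",
              x$acquisition$frame_interval, x$acquisition$focal_depth))
  invisible(x)
}
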