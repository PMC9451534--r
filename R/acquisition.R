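#' Acquisition parameters for an SPT experiment
#'
#' Bundles the imaging metadata needed to interpret a trajectory table:
#' the frame interval, the camera pixel size, the focal (detection) depth
#' of the objective, and the first frame retained on import.
#'
#' @param frame_interval Frame interval in seconds. Defaults to 7.48 ms,
#'   a typical stroboscopic sptPALM setting.
#' @param pixel_size Camera pixel size in micrometers per pixel.
#' @param focal_depth Depth of the focal slab in micrometers within which
#'   emitters are detected.
#' @param start_frame Integer frame index; detections on earlier frames
#'   are discarded on import (use 0 to keep everything).  Experimental
#'   imports commonly discard an initial high-density photoactivation
#'   phase; simulated data keep all frames.
#'
#' @return An object of class `sa_acquisition`.
#' @examples
#' acq <- acquisition_params(frame_interval = 0.00748, pixel_size = 0.16)
#' acq$frame_interval
#' @export
acquisition_params <- function(frame_interval = 0.00748,
                               pixel_size = 0.16,
                               focal_depth = 0.7,
                               start_frame = 0L) {
  stopifnot(
    "frame_interval must be a single positive number" =
      is.numeric(frame_interval) && length(frame_interval) == 1L && frame_interval > 0,
    "pixel_size must be a single positive number" =
      is.numeric(pixel_size) && length(pixel_size) == 1L && pixel_size > 0,
    "focal_depth must be a single positive number" =
      is.numeric(focal_depth) && length(focal_depth) == 1L && focal_depth > 0,
    "start_frame must be a single nonnegative integer" =
      is.numeric(start_frame) && length(start_frame) == 1L &&
        start_frame >= 0 && start_frame == as.integer(start_frame)
  )
  structure(
    list(
      frame_interval = as.numeric(frame_interval),
      pixel_size = as.numeric(pixel_size),
      focal_depth = as.numeric(focal_depth),
      start_frame = as.integer(start_frame)
    ),
    class = "sa_acquisition"
  )
}

#' @export
print.sa_acquisition <- function(x, ...) {
  cat("Acquisition parameters\n")
  cat(sprintf("  frame interval: %g s\n", x$frame_interval))
  cat(sprintf("  pixel size:     %g um\n", x$pixel_size))
  cat(sprintf("  focal depth:    %g um\n", x$focal_depth))
  cat(sprintf("  start frame:    %d\n", x$start_frame))
  invisible(x)
}
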