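#' Read a trajectory table from a delimited text file
#'
#' Reads CSV/TSV trajectory tables in either of two dialects, detected
#' from the header:
#' \describe{
#'   \item{tracking-pipeline dialect}{columns `trajectory`, `frame`,
#'     `y`, `x`, positions in pixels (the convention of common SPT
#'     detection/linking pipelines).}
#'   \item{plain dialect}{columns `id` (or `trajectory`), `frame`,
#'     `x_um`, `y_um`, positions in micrometers.}
#' }
#' When the plain dialect is detected, positions are taken as
#' micrometers regardless of `unit`.
#'
#' @param path Path to a delimited text file.
#' @param acquisition An [acquisition_params()] object.  Its
#'   `start_frame` controls how many initial frames are discarded.
#' @param unit `"pixels"` or `"um"`; how to interpret `x`/`y` columns in
#'   the tracking-pipeline dialect.
#' @return An `sa_dataset`; see [trajectory_dataset()].
#' @export
read_trajectories <- function(path, acquisition, unit = c("pixels", "um")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    data.table::fread(path, data.table = FALSE, showProgress = FALSE),
    error = function(e) stop("failed to parse '", path, "': ", conditionMessage(e))
  )
  if (nrow(raw) == 0) stop("empty trajectory file: ", path)
  nm <- names(raw)

  if (all(c("x_um", "y_um") %in% nm)) {
    idcol <- if ("id" %in% nm) "id" else if ("trajectory" %in% nm) "trajectory" else
      stop("plain-dialect file lacks an 'id' or 'trajectory' column")
    if (!"frame" %in% nm) stop("trajectory file lacks a 'frame' column")
    df <- data.frame(trajectory = raw[[idcol]], frame = raw[["frame"]],
                     x = raw[["x_um"]], y = raw[["y_um"]])
    unit <- "um"
  } else if (all(c("trajectory", "frame", "x", "y") %in% nm)) {
    df <- raw[, c("trajectory", "frame", "x", "y")]
  } else {
    stop("unrecognized trajectory table header: need columns ",
         "trajectory/frame/x/y or id/frame/x_um/y_um; found: ",
         paste(nm, collapse = ", "))
  }
  for (cc in c("frame", "x", "y"))
    if (!is.numeric(df[[cc]]))
      stop("non-numeric values in column '", cc, "' of ", path)
  trajectory_dataset(df, acquisition, unit = unit)
}

#' Write a trajectory dataset to CSV
#'
#' Writes the plain dialect (`id`, `frame`, `x_um`, `y_um`) with full
#' double precision so that a write/read round trip reproduces the
#' positions exactly.
#'
#' @param ds An `sa_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ds, path) {
  stopifnot(inherits(ds, "sa_dataset"))
  out <- data.frame(
    id = ds$positions$trajectory,
    frame = ds$positions$frame,
    x_um = sprintf("%.17g", ds$positions$x),
    y_um = sprintf("%.17g", ds$positions$y)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an occupation profile to CSV
#'
#' @param profile An `occupation_profile`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "occupation_profile"))
  out <- cbind(profile$states, occupation = profile$occupations)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
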