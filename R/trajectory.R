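#' Construct a trajectory
#'
#' A trajectory is one molecule's time-ordered 2-D localizations in
#' micrometres, with integer frame indices and the acquisition frame
#' interval. Coordinates are continuous physical units; the origin is
#' arbitrary.
#'
#' @param track_id Identifier (scalar).
#' @param frames Strictly increasing integer frame indices.
#' @param x,y Coordinates in micrometres, one per frame.
#' @param frame_interval Frame interval in seconds.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(track_id, frames, x, y, frame_interval) {
  frames <- as.integer(frames)
  if (length(x) != length(frames) || length(y) != length(frames))
    stop("x, y and frames must have equal length")
  if (length(frames) > 1L && any(diff(frames) <= 0L))
    stop(sprintf("track %s: frames must be strictly increasing", track_id))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop(sprintf("track %s: non-finite coordinates", track_id))
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(
    list(track_id = track_id, frames = frames,
         x = as.numeric(x), y = as.numeric(y),
         frame_interval = frame_interval),
    class = "trajectory"
  )
}

#' Number of localizations in a trajectory
#' @param traj A `trajectory`.
#' @return Integer count.
#' @export
n_points <- function(traj) length(traj$frames)

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d points, dt=%g s>\n",
              x$track_id, n_points(x), x$frame_interval))
  invisible(x)
}

#' Translate a trajectory so it starts at the origin
#'
#' Subtracts the first coordinate from every localization, leaving all
#' inter-point displacements unchanged. Applied before rendering so that
#' every trajectory image is anchored at the canvas centre.
#'
#' @param traj A `trajectory`.
#' @return The standardized `trajectory` (first point at (0, 0)).
#' @export
standardize <- function(traj) {
  stopifnot(inherits(traj, "trajectory"), n_points(traj) >= 1L)
  traj$x <- traj$x - traj$x[1L]
  traj$y <- traj$y - traj$y[1L]
  traj
}

#' Rotate a trajectory about the origin
#' @param traj A standardized `trajectory`.
#' @param theta Rotation angle in radians (counter-clockwise).
#' @return The rotated `trajectory`.
#' @export
rotate_trajectory <- function(traj, theta) {
  co <- cos(theta); si <- sin(theta)
  x <- traj$x * co - traj$y * si
  y <- traj$x * si + traj$y * co
  traj$x <- x; traj$y <- y
  traj
}

# character track ids of a trajectory list
track_ids <- function(trs)
  vapply(trs, function(t) as.character(t[["track_id"]]), "")
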