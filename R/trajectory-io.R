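# Track-table I/O, ROI and track-quality filtering shared by all analyses.
#
# CSV dialect: header `track_id,frame,x_um,y_um`, UTF-8, '.' decimal
# separator, optional leading `#`-prefixed metadata lines of the form
# `# key=value` (e.g. `# frame_interval_s=0.01`).

#' Rectangular region of interest
#'
#' Axis-aligned rectangle in micrometres; the default 3 um width is the
#' irradiated-band geometry, with the height limited by the nucleus
#' border.
#'
#' @param center Length-2 numeric, centre (um).
#' @param width,height Rectangle sides (um), both > 0.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(center = c(0, 0), width = 3, height = 12) {
  if (width <= 0 || height <= 0) stop("ROI width and height must be > 0")
  structure(list(center = as.numeric(center), width = width, height = height),
            class = "rect_roi")
}

roi_contains <- function(roi, x, y) {
  abs(x - roi$center[1]) <= roi$width / 2 &
    abs(y - roi$center[2]) <= roi$height / 2
}

#' Build a track table
#'
#' @param track_id,frame,x_um,y_um Column vectors.
#' @param frame_interval Frame interval (s), stored as metadata.
#' @param pixel_size Pixel size (um), stored as metadata.
#' @param condition,timepoint Optional labels, stored as metadata.
#' @return A `track_table` (data.frame with metadata attributes).
#' @export
track_table <- function(track_id, frame, x_um, y_um,
                        frame_interval = 0.01, pixel_size = 0.160,
                        condition = NA_character_, timepoint = NA_character_) {
  df <- data.frame(track_id = as.character(track_id),
                   frame = as.integer(frame),
                   x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   stringsAsFactors = FALSE)
  validate_track_table(df)
  attr(df, "frame_interval") <- frame_interval
  attr(df, "pixel_size") <- pixel_size
  attr(df, "condition") <- condition
  attr(df, "timepoint") <- timepoint
  class(df) <- c("track_table", "data.frame")
  df
}

validate_track_table <- function(df) {
  if (!all(c("track_id", "frame", "x_um", "y_um") %in% names(df)))
    stop("track table requires columns track_id, frame, x_um, y_um")
  if (anyDuplicated(df[c("track_id", "frame")])) {
    bad <- df$track_id[duplicated(df[c("track_id", "frame")])][1]
    stop(sprintf("duplicated (track_id, frame) in track %s", bad))
  }
  ord <- unlist(tapply(df$frame, df$track_id,
                       function(f) all(diff(f) > 0), simplify = FALSE))
  if (!all(ord))
    stop(sprintf("non-increasing frames in track %s",
                 names(ord)[which(!ord)[1]]))
  invisible(df)
}

tt_meta <- function(tt)
  list(frame_interval = attr(tt, "frame_interval"),
       pixel_size = attr(tt, "pixel_size"),
       condition = attr(tt, "condition"),
       timepoint = attr(tt, "timepoint"))

#' Write a track table to CSV
#'
#' Emits `# key=value` metadata lines followed by the standard header.
#' Coordinates are written with 6 decimal places, so a write/read
#' round-trip is lossless at that precision.
#'
#' @param table A `track_table`.
#' @param path Output file.
#' @export
write_tracks <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  m <- tt_meta(table)
  writeLines(sprintf("# frame_interval_s=%g", m$frame_interval), con)
  writeLines(sprintf("# pixel_size_um=%g", m$pixel_size), con)
  if (!is.na(m$condition)) writeLines(sprintf("# condition=%s", m$condition), con)
  if (!is.na(m$timepoint)) writeLines(sprintf("# timepoint=%s", m$timepoint), con)
  writeLines("track_id,frame,x_um,y_um", con)
  writeLines(sprintf("%s,%d,%.6f,%.6f", table$track_id, table$frame,
                     table$x_um, table$y_um), con)
  invisible(path)
}

#' Read a track table from CSV
#'
#' Accepts the package dialect (`track_id,frame,x_um,y_um`, optional
#' `# key=value` metadata lines). Coordinates may instead be supplied in
#' pixels as columns `x_px,y_px`, converted with `pixel_size`.
#'
#' @param path Input file.
#' @param frame_interval,pixel_size Metadata overrides; when `NULL`, taken
#'   from `#` metadata lines (defaults 0.01 s / 0.160 um).
#' @param condition,timepoint Optional labels.
#' @return A `track_table`.
#' @export
read_tracks <- function(path, frame_interval = NULL, pixel_size = NULL,
                        condition = NA_character_, timepoint = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(frame_interval))
    frame_interval <- as.numeric(meta[["frame_interval_s"]] %||% 0.01)
  if (is.null(pixel_size))
    pixel_size <- as.numeric(meta[["pixel_size_um"]] %||% 0.160)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  if (!"x_um" %in% names(df) && all(c("x_px", "y_px") %in% names(df))) {
    df$x_um <- df$x_px * pixel_size
    df$y_um <- df$y_px * pixel_size
  }
  if (!all(c("track_id", "frame", "x_um", "y_um") %in% names(df)))
    stop("track table requires columns track_id, frame, x_um, y_um ",
         "(or x_px, y_px with a pixel size)")
  track_table(df$track_id, df$frame, df$x_um, df$y_um,
              frame_interval = frame_interval, pixel_size = pixel_size,
              condition = condition %||% meta[["condition"]] %||% NA_character_,
              timepoint = timepoint %||% meta[["timepoint"]] %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read a TrackMate-style spot table
#'
#' Convenience reader for CSV exports with columns `TRACK_ID`, `FRAME`,
#' `POSITION_X`, `POSITION_Y`. Positions are interpreted in the declared
#' `units` ("um" or "px"; pixel positions are converted with
#' `pixel_size`).
#'
#' @param path Input file.
#' @param units "um" or "px".
#' @param frame_interval Frame interval (s).
#' @param pixel_size Pixel size (um).
#' @return A `track_table`.
#' @export
read_tracks_trackmate <- function(path, units = c("um", "px"),
                                  frame_interval = 0.01, pixel_size = 0.160) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% names(df)))
    stop("TrackMate table requires columns ", paste(need, collapse = ", "))
  sc <- if (units == "px") pixel_size else 1
  df <- df[order(df$TRACK_ID, df$FRAME), ]
  track_table(df$TRACK_ID, df$FRAME, df$POSITION_X * sc, df$POSITION_Y * sc,
              frame_interval = frame_interval, pixel_size = pixel_size)
}

#' Filter tracks by ROI membership
#'
#' A track is retained iff its time-averaged centroid lies inside
#' (`mode = "inside"`) or outside (`mode = "outside"`) the rectangle, so
#' tracks straddling the boundary are resolved by the centroid rule and
#' the two modes partition any table.
#'
#' @param table A `track_table`.
#' @param roi A [rect_roi()].
#' @param mode "inside" or "outside".
#' @return The filtered `track_table` (empty with a warning when nothing
#'   is retained).
#' @export
filter_by_roi <- function(table, roi, mode = c("inside", "outside")) {
  mode <- match.arg(mode)
  cx <- tapply(table$x_um, table$track_id, mean)
  cy <- tapply(table$y_um, table$track_id, mean)
  inside <- roi_contains(roi, cx, cy)
  keep <- names(cx)[if (mode == "inside") inside else !inside]
  out <- table[table$track_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0) warning("ROI filter retained no tracks")
  rebuild_tt(out, table)
}

#' Filter tracks by minimum length
#'
#' @param table A `track_table`.
#' @param min_points Minimum localizations per track (>= 2). The default 5
#'   is the package-wide minimum for classification and jump statistics.
#' @return The filtered `track_table`; the number of removed tracks is
#'   reported via `message()` and the `"n_removed"` attribute.
#' @export
filter_by_length <- function(table, min_points = 5L) {
  if (min_points < 2L) stop("min_points must be >= 2")
  len <- table(table$track_id)
  keep <- names(len)[len >= min_points]
  n_removed <- length(len) - length(keep)
  out <- table[table$track_id %in% keep, , drop = FALSE]
  if (length(keep) == 0) warning("length filter retained no tracks")
  if (n_removed > 0)
    message(sprintf("filter_by_length: removed %d of %d tracks",
                    n_removed, length(len)))
  out <- rebuild_tt(out, table)
  attr(out, "n_removed") <- n_removed
  out
}

rebuild_tt <- function(df, template) {
  m <- tt_meta(template)
  rownames(df) <- NULL
  attr(df, "frame_interval") <- m$frame_interval
  attr(df, "pixel_size") <- m$pixel_size
  attr(df, "condition") <- m$condition
  attr(df, "timepoint") <- m$timepoint
  class(df) <- c("track_table", "data.frame")
  df
}

#' Convert a track collection to a track table
#' @param collection A `track_collection` from the simulator.
#' @return A `track_table`.
#' @export
as_track_table <- function(collection) {
  trs <- collection$tracks
  n <- vapply(trs, n_points, 0L)
  track_table(
    rep(track_ids(trs), n),
    unlist(lapply(trs, `[[`, "frames")),
    unlist(lapply(trs, `[[`, "x")),
    unlist(lapply(trs, `[[`, "y")),
    frame_interval = collection$config$frame_interval,
    pixel_size = collection$config$pixel_size
  )
}

#' Split a track table into trajectory objects
#' @param table A `track_table`.
#' @return Named list of [trajectory()].
#' @export
as_trajectories <- function(table) {
  dt <- attr(table, "frame_interval") %||% 0.01
  ids <- unique(table$track_id)
  out <- lapply(ids, function(id) {
    s <- table[table$track_id == id, ]
    trajectory(id, s$frame, s$x_um, s$y_um, dt)
  })
  names(out) <- ids
  out
}
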