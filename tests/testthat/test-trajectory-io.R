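# Track-table I/O, ROI filtering and track-quality filtering.

make_fixture_table <- function() {
  track_table(
    track_id = rep(c("a", "b", "c"), times = c(3, 8, 20)),
    frame = c(0:2, 0:7, 0:19),
    x_um = c(rnorm(3, 0), rnorm(8, 5), rnorm(20, -4, 0.1)),
    y_um = c(rnorm(3, 0), rnorm(8, 0), rnorm(20, 2, 0.1)),
    frame_interval = 0.01, pixel_size = 0.16
  )
}

test_that("write/read round-trip is lossless to 6 decimals", {
  set.seed(1)
  tt <- make_fixture_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tt, path)
  back <- read_tracks(path)
  expect_equal(back$track_id, tt$track_id)
  expect_equal(back$frame, tt$frame)
  expect_equal(back$x_um, tt$x_um, tolerance = 1e-6)
  expect_equal(back$y_um, tt$y_um, tolerance = 1e-6)
  expect_equal(attr(back, "frame_interval"), 0.01)
  expect_equal(attr(back, "pixel_size"), 0.16)
})

test_that("pixel-unit files are converted with the configured pixel size", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# pixel_size_um=0.16", "track_id,frame,x_px,y_px",
               "a,0,10,20", "a,1,11,20"), path)
  tt <- read_tracks(path)
  expect_equal(tt$x_um, c(1.60, 1.76))
  expect_equal(tt$y_um, c(3.20, 3.20))
})

test_that("malformed tables are rejected with the offending track named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_um,y_um",
               "bad,3,0,0", "bad,2,0,0", "bad,1,0,0"), path)
  expect_error(read_tracks(path), "bad")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_um,y_um", "d,1,0,0", "d,1,1,1"), path2)
  expect_error(read_tracks(path2), "d")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_wrong", "a,1,0"), path3)
  expect_error(read_tracks(path3), "columns")
})

test_that("TrackMate-style tables import with unit conversion", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TRACK_ID,FRAME,POSITION_X,POSITION_Y",
               "1,0,10,0", "1,1,10,5"), path)
  tt <- read_tracks_trackmate(path, units = "px", pixel_size = 0.2)
  expect_equal(tt$x_um, c(2, 2))
  expect_equal(tt$y_um, c(0, 1))
})

test_that("ROI filtering follows the centroid rule and partitions the table", {
  roi <- rect_roi(center = c(0, 0), width = 2, height = 2)
  # track centred at the ROI centre: retained inside
  tt <- track_table(rep(c("in", "straddle"), each = 2), c(0, 1, 0, 1),
                    x_um = c(-0.1, 0.1, 0.9, 1.3),  # straddle centroid 1.1 > 1
                    y_um = c(0, 0, 0, 0))
  ins <- filter_by_roi(tt, roi, "inside")
  expect_equal(unique(ins$track_id), "in")
  out <- filter_by_roi(tt, roi, "outside")
  expect_equal(unique(out$track_id), "straddle")
  # partition property on a random table
  set.seed(2)
  big <- make_fixture_table()
  a <- suppressWarnings(filter_by_roi(big, roi, "inside"))
  b <- suppressWarnings(filter_by_roi(big, roi, "outside"))
  expect_equal(sort(c(unique(a$track_id), unique(b$track_id))),
               sort(unique(big$track_id)))
  expect_length(intersect(unique(a$track_id), unique(b$track_id)), 0)
  # idempotence
  expect_equal(filter_by_roi(ins, roi, "inside")$track_id, ins$track_id)
})

test_that("length filtering retains exactly the long-enough tracks", {
  set.seed(3)
  tt <- make_fixture_table()   # lengths 3, 8, 20
  f2 <- filter_by_length(tt, 2)
  expect_equal(sort(unique(f2$track_id)), c("a", "b", "c"))
  f8 <- suppressMessages(filter_by_length(tt, 8))
  expect_equal(sort(unique(f8$track_id)), c("b", "c"))
  expect_equal(attr(f8, "n_removed"), 1L)
  expect_warning(suppressMessages(filter_by_length(tt, 50)), "no tracks")
  # idempotence
  expect_equal(suppressMessages(filter_by_length(f8, 8))$track_id, f8$track_id)
})

test_that("labels survive a table round-trip through the collection", {
  cfg <- sim_config(n_tracks = 40, seed = 12)
  pop <- simulate_population(cfg)
  tt <- as_track_table(pop)
  trs <- as_trajectories(tt)
  expect_equal(length(trs), nrow(pop$labels))
  expect_equal(names(trs), pop$labels$track_id)
  expect_equal(vapply(trs, n_points, 0L), setNames(pop$labels$n_points,
                                                   pop$labels$track_id))
})
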