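# Line segmentation, moment-ellipse thickness, thickness series and
# recruitment curves.

# brute-force second-moment minor axis (independent oracle)
minor_axis_oracle <- function(mask, pixel_size = 1) {
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2]; ys <- idx[, 1]
  # integrate x^2 over each unit pixel: Var(centre) + 1/12
  cxx <- mean(xs^2) - mean(xs)^2 + 1 / 12
  cyy <- mean(ys^2) - mean(ys)^2 + 1 / 12
  cxy <- mean(xs * ys) - mean(xs) * mean(ys)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
  4 * sqrt(min(ev)) * pixel_size
}

test_that("k-means segmentation recovers a separable band exactly", {
  img <- matrix(100, 64, 64)
  img[30:33, ] <- 1000
  mask <- segment_line(img)
  expect_false(attr(mask, "unsegmentable"))
  truth <- matrix(FALSE, 64, 64); truth[30:33, ] <- TRUE
  expect_equal(unname(mask), truth, ignore_attr = TRUE)
})

test_that("single-population frames are flagged unsegmentable", {
  set.seed(61)
  noise <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  expect_warning(m <- segment_line(noise), "unsegmentable")
  expect_true(attr(m, "unsegmentable"))
  expect_error(segment_line(matrix(1, 10, 10)), "variance")
})

test_that("noisy band segmentation overlaps the true band (Jaccard >= 0.9)", {
  cfg <- image_sim_config(image_shape = c(96L, 96L), pixel_size = 0.1,
                          line_width_profile = 1.2, psf_sigma = 0.05,
                          intensity_fg = 1000, intensity_bg = 100,
                          read_noise_sd = 10, seed = 3)
  ser <- simulate_line_images(cfg)
  mask <- segment_line(ser$frames[[1]])
  yc <- (seq_len(96) - 0.5) * 0.1
  truth <- matrix(rep(abs(yc - 4.8) <= 0.6, 96), 96, 96)
  jac <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jac, 0.9)
})

test_that("moment-ellipse thickness matches closed forms and the oracle", {
  # solid axis-aligned rectangle, 4 px tall: minor axis 2 h / sqrt(3)
  m <- matrix(FALSE, 64, 64); m[30:33, 10:59] <- TRUE
  th <- thickness_from_mask(m, pixel_size = 1)
  expect_equal(th, 2 * 4 / sqrt(3), tolerance = 0.02)
  expect_equal(th, minor_axis_oracle(m), tolerance = 1e-12)
  # rotation invariance: the same rectangle rotated 30 degrees
  ang <- 30 * pi / 180
  rot <- matrix(FALSE, 96, 96)
  for (i in 1:96) for (j in 1:96) {
    # rotate pixel centre back into the rectangle frame
    x <- (j - 48.5) * cos(ang) + (i - 48.5) * sin(ang)
    y <- -(j - 48.5) * sin(ang) + (i - 48.5) * cos(ang)
    rot[i, j] <- abs(y) <= 2 && abs(x) <= 25
  }
  expect_equal(thickness_from_mask(rot, 1), 2 * 4 / sqrt(3), tolerance = 0.05)
  # disk of diameter d: minor axis = d
  disk <- matrix(FALSE, 64, 64)
  for (i in 1:64) for (j in 1:64)
    disk[i, j] <- (i - 32.5)^2 + (j - 32.5)^2 <= 15^2
  expect_equal(thickness_from_mask(disk, 1), 30, tolerance = 0.03)
  # tiny mask flagged
  tiny <- matrix(FALSE, 8, 8); tiny[4, 4:6] <- TRUE
  expect_warning(res <- thickness_from_mask(tiny), "flagged")
  expect_true(is.na(res))
})

test_that("constant-width series normalizes to 1 and a programmed step is recovered", {
  cfg0 <- image_sim_config(line_width_profile = rep(1, 6), psf_sigma = 0.1,
                           poisson = FALSE, read_noise_sd = 0, seed = 1)
  th0 <- thickness_series(simulate_line_images(cfg0))
  expect_equal(th0$normalized, rep(1, 6), tolerance = 1e-6)
  expect_equal(th0$normalized[1], 1)
  # programmed 1.4x widening at high SNR recovered within 5%
  prof <- c(1, 1, 1.4, 1.4, 1)
  cfg1 <- image_sim_config(line_width_profile = prof, psf_sigma = 0.1,
                           intensity_fg = 5000, intensity_bg = 100,
                           read_noise_sd = 2, seed = 2)
  th1 <- thickness_series(simulate_line_images(cfg1))
  expect_equal(th1$normalized[3], 1.4, tolerance = 0.05)
  expect_equal(th1$normalized[5], 1.0, tolerance = 0.05)
})

test_that("thickness estimate is invariant under affine intensity rescaling", {
  cfg <- image_sim_config(line_width_profile = 1.0, psf_sigma = 0.05,
                          read_noise_sd = 5, seed = 9)
  fr <- simulate_line_images(cfg)$frames[[1]]
  t1 <- thickness_from_mask(segment_line(fr), 0.1)
  t2 <- thickness_from_mask(segment_line(fr * 3.7 + 50), 0.1)
  expect_equal(t1, t2)
})

test_that("recruitment curve cancels photobleaching and normalizes pre-damage to 1", {
  # synthetic nucleus: uniform 100 inside, 10 outside; ROI enriched 2x
  # after frame 2 while the whole frame bleaches to 50%
  nr <- 40
  nucleus <- matrix(FALSE, nr, nr); nucleus[6:35, 6:35] <- TRUE
  roi <- matrix(FALSE, nr, nr); roi[18:23, 6:35] <- TRUE
  bg <- matrix(FALSE, nr, nr); bg[1:3, 1:3] <- TRUE
  frames <- lapply(1:6, function(f) {
    bleach <- if (f > 2) 0.5 else 1
    img <- matrix(5, nr, nr)
    img[nucleus] <- 100 * bleach
    img[roi] <- 100 * bleach * (if (f > 2) 2 else 1)
    img
  })
  series <- structure(list(frames = frames, pixel_size = 0.1,
                           timestamps = 0:5, irradiation_frame = 3L,
                           truth = NULL), class = "nucleus_image_series")
  rc <- recruitment_curve(series, roi, nucleus & !roi, bg,
                          predamage_frames = 1:2)
  expect_equal(rc$recruitment[1:2], c(1, 1), tolerance = 1e-10)
  expect_equal(rc$recruitment[3:6], rep(2, 4), tolerance = 0.1)
  # scaling every frame by a positive constant changes nothing
  series2 <- series; series2$frames <- lapply(frames, function(f) 4.2 * f)
  rc2 <- recruitment_curve(series2, roi, nucleus & !roi, bg, 1:2)
  expect_equal(rc2$recruitment, rc$recruitment, tolerance = 1e-12)
})

test_that("line images validate their configuration", {
  expect_error(image_sim_config(line_width_profile = c(1, -1)), "positive")
  expect_error(image_sim_config(image_shape = c(32L, 32L), pixel_size = 0.1,
                                line_width_profile = 5), "thicker")
})

test_that("normalized thickness stays within 5% median error across SNR levels", {
  prof <- c(1, 1.2, 1.4, 1.1, 0.95)
  for (snr in c(5, 10, 20)) {
    # peak SNR = (fg - bg)/sqrt(fg) with Poisson shot noise
    fg <- ((snr + sqrt(snr^2 + 400)) / 2)^2
    cfg <- image_sim_config(line_width_profile = prof, psf_sigma = 0.1,
                            intensity_fg = fg, intensity_bg = 100,
                            read_noise_sd = 2, seed = 600 + snr)
    th <- thickness_series(simulate_line_images(cfg))
    err <- abs(th$normalized - prof / prof[1])
    expect_lte(median(err, na.rm = TRUE), 0.05)
  }
})
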