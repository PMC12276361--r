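# Rendering, augmentation, the CNN surface, and the segment-threshold
# baseline. The expensive trained model comes from the shared fixture.

test_that("instantaneous diffusion matches hand values and the channel rule", {
  expect_equal(instantaneous_diffusion(0.2, 0, 0.01), 1.0)
  expect_equal(instantaneous_diffusion(0, 0, 0.01), 0)
  expect_equal(instantaneous_diffusion(0.3, 0.4, 0.01), 6.25)
  expect_error(instantaneous_diffusion(1, 1, 0), "dt")
  # boundary values belong to the lower-named channel
  tr <- traj_from_xy(c(0, 0.2, 0.2, 0.5), c(0, 0, 0, 0.4))
  # steps: dx 0.2 (D=1) green; dx 0 (D=0) red; (0.3,0.4) D=6.25 blue
  expect_equal(nucleodyn:::segment_channels(tr), c(2L, 1L, 3L))
  tr2 <- traj_from_xy(c(0, sqrt(4 * 0.01 * 0.5)), c(0, 0))  # D = 0.5 exactly
  expect_equal(nucleodyn:::segment_channels(tr2), 1L)
})

test_that("standardization anchors at the origin and is idempotent", {
  tr <- traj_from_xy(c(3, 4, 5), c(-2, -1, 0))
  s <- standardize(tr)
  expect_equal(c(s$x[1], s$y[1]), c(0, 0))
  expect_equal(diff(s$x), diff(tr$x))
  expect_equal(diff(s$y), diff(tr$y))
  expect_identical(standardize(s), s)
})

test_that("rotation augmentation preserves distances and segment colors", {
  set.seed(31)
  tr <- standardize(traj_from_xy(cumsum(rnorm(12, 0, 0.1)),
                                 cumsum(rnorm(12, 0, 0.1))))
  rots <- augment_rotations(tr, 23)
  expect_length(rots, 23)
  d0 <- dist(cbind(tr$x, tr$y))
  ch0 <- nucleodyn:::segment_channels(tr)
  for (r in rots[c(1, 11, 23)]) {
    expect_equal(as.numeric(dist(cbind(r$x, r$y))), as.numeric(d0))
    expect_equal(nucleodyn:::segment_channels(r), ch0)
  }
  # a full 2 pi rotation reproduces the input to machine precision
  full <- rotate_trajectory(tr, 2 * pi)
  expect_equal(full$x, tr$x, tolerance = 1e-12)
  expect_equal(full$y, tr$y, tolerance = 1e-12)
})

test_that("rendering draws monochromatic sub-pixel segments and clips cleanly", {
  rc <- render_config(image_size = 128L, window_um = 2)
  # single-point track: blank with warning
  tr1 <- traj_from_xy(0.5, 0.5)
  expect_warning(img1 <- render(tr1, rc), "single point")
  expect_equal(sum(img1), 0)
  # slow 2-point track: red channel only
  tr2 <- traj_from_xy(c(0, 0.1), c(0, 0))   # D = 0.25
  img2 <- render(tr2, rc)
  expect_gt(sum(img2[, , 1]), 0)
  expect_equal(sum(img2[, , 2]), 0)
  expect_equal(sum(img2[, , 3]), 0)
  # 3-point track with D 0.25 then 6.25: red and blue segments
  tr3 <- traj_from_xy(c(0, 0.1, 0.6), c(0, 0, 0))
  img3 <- render(tr3, rc)
  expect_gt(sum(img3[, , 1]), 0)
  expect_equal(sum(img3[, , 2]), 0)
  expect_gt(sum(img3[, , 3]), 0)
  # fixed-window rendering clips out-of-window tracks with a warning;
  # the default auto-expanding window keeps them fully in view
  trbig <- traj_from_xy(c(0, 5), c(0, 0))
  rc_fix <- render_config(image_size = 128L, window_um = 2,
                          auto_expand = FALSE)
  expect_warning(render(trbig, rc_fix), "clip")
  expect_silent(imgbig <- render(trbig, rc))
  expect_gt(sum(imgbig), 0)
})

test_that("rendering is equivariant under quarter-turn rotation", {
  set.seed(32)
  tr <- standardize(traj_from_xy(cumsum(rnorm(10, 0, 0.08)),
                                 cumsum(rnorm(10, 0, 0.08))))
  rc <- render_config(image_size = 128L, window_um = 2)
  img <- render(tr, rc)
  img90 <- render(rotate_trajectory(tr, pi / 2), rc)
  # rotating the canvas by 90 degrees: (x, y) -> (-y, x); for the pixel
  # array (row = y, col = x) this maps img[y, x] to img90[x, size + 1 - y]
  S <- 128L
  rot <- array(0, dim(img))
  for (ch in 1:3) rot[, , ch] <- t(img[, , ch])[, S:1]
  # rasterization tolerance: mirroring flips the bilinear splat
  # alignment by up to one pixel, so allow an integer shift and a
  # sub-pixel residual on the overlap
  shifted <- function(m, dy, dx) {
    out <- matrix(0, S, S)
    rs <- max(1, 1 + dy):min(S, S + dy); cs <- max(1, 1 + dx):min(S, S + dx)
    out[rs, cs] <- m[rs - dy, cs - dx]
    out
  }
  for (ch in 1:3) {
    a <- rot[, , ch]; b <- img90[, , ch]
    if (sum(a) + sum(b) == 0) next
    best <- min(sapply(-1:1, function(dy) sapply(-1:1, function(dx)
      sum(abs(shifted(a, dy, dx) - b)))))
    expect_lt(best / (sum(a) + sum(b)), 0.15)
  }
})

test_that("untrained network emits valid probabilities sensitive to channel order", {
  m <- build_model(train_config(image_size = 128L, seed = 5L))
  set.seed(33)
  tr <- simulate_fbm_track(12, sim_config(seed = 33), track_id = "p")
  out <- classify(m, tr)
  p <- unlist(out[1, c("p_immobile", "p_hybrid", "p_mobile")])
  expect_equal(sum(p), 1, tolerance = 1e-5)
  expect_true(all(p >= 0))
  # permuting input channels changes the forward pass (channels are semantic)
  rc <- m$render
  s <- standardize(tr)
  ch <- nucleodyn:::segment_channels(s, rc$d_thresholds)
  img <- nucleodyn:::render_traj_cpp(cbind(s$x, s$y), ch, 128L,
                                     rc$window_um, rc$step_px)
  arr <- array(img, c(128, 128, 3, 1))
  arr_perm <- arr[, , c(3, 1, 2), , drop = FALSE]
  p1 <- nucleodyn:::htc_predict(nucleodyn:::model_ptr(m), arr)
  p2 <- nucleodyn:::htc_predict(nucleodyn:::model_ptr(m), arr_perm)
  expect_false(isTRUE(all.equal(p1, p2, tolerance = 1e-8)))
})

test_that("single-class training is rejected", {
  cfg <- sim_config(seed = 40)
  trs <- lapply(1:10, function(i) simulate_fbm_track(8, cfg, track_id = i))
  expect_error(train_classifier(trs, train_config(image_size = 128L),
                                labels = rep("immobile", 10)),
               "two classes")
})

test_that("baseline mapping rule follows the segment labels", {
  # all segments slow: immobile (raw rule, no smoothing)
  tr_imm <- traj_from_xy(c(0, 0.05, 0.1, 0.15, 0.2), rep(0, 5))
  expect_equal(baseline_classify_segments(tr_imm, min_run = 1)$label,
               "immobile")
  # D sequence 0.25, 6.25, 0.25: hybrid
  tr_hyb <- traj_from_xy(c(0, 0.1, 0.6, 0.7), rep(0, 4))
  expect_equal(baseline_classify_segments(tr_hyb, min_run = 1)$label,
               "hybrid")
  # all fast: mobile
  tr_mob <- traj_from_xy(c(0, 0.5, 1.0, 1.5), rep(0, 4))
  expect_equal(baseline_classify_segments(tr_mob, min_run = 1)$label,
               "mobile")
  pr <- baseline_classify_segments(tr_mob, min_run = 1)$probabilities
  expect_equal(sum(pr), 1)
})

test_that("baseline agrees with ground truth on default synthetic data", {
  cfg <- sim_config(n_tracks = 1200, seed = 50)
  pop <- simulate_population(cfg)
  keep <- pop$labels$n_points >= 5L
  trs <- pop$tracks[keep]
  truth <- pop$labels$true_label[keep]
  pred <- vapply(trs, function(t) baseline_classify_segments(t)$label, "")
  expect_gte(mean(pred == truth), 0.95)
})

test_that("model save/load round-trips the serialized state", {
  m <- build_model(train_config(image_size = 128L, seed = 6L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_htc_model(m, path)
  m2 <- load_htc_model(path)
  expect_equal(m2$state$Wd, m$state$Wd)
  expect_equal(m2$render, m$render)
  # both instances produce identical predictions
  set.seed(41)
  tr <- simulate_fbm_track(10, sim_config(seed = 41), track_id = "rt")
  expect_equal(classify(m, tr), classify(m2, tr))
})
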