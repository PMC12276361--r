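# Synthetic track generator: exact fBm statistics, hybrid switching,
# population structure, and reproducibility.

test_that("fBm generator matches the closed-form ensemble MSD on a parameter grid", {
  cfg <- quiet_config(seed = 1)
  n_rep <- 400L; n_steps <- 32L
  lags <- c(1L, 2L, 4L, 8L, 16L)
  for (alpha in c(0.5, 1.0, 1.5)) {
    for (A in c(0.004, 0.04)) {
      set.seed(1000 + round(1000 * alpha) + round(1e5 * A))
      per_track <- matrix(NA_real_, n_rep, length(lags))
      for (r in seq_len(n_rep)) {
        tr <- simulate_fbm_track(n_steps, cfg, alpha = alpha, A = A)
        m <- compute_tamsd(tr, max_lag = max(lags))
        per_track[r, ] <- m$msd[lags]
      }
      obs <- colMeans(per_track)
      se <- apply(per_track, 2, stats::sd) / sqrt(n_rep)
      theo <- A * (lags * cfg$frame_interval)^alpha
      expect_true(all(abs(obs - theo) <= 3 * se),
                  info = sprintf("alpha=%g A=%g", alpha, A))
    }
  }
})

test_that("Brownian special case reproduces MSD = 4 D t at the first lag", {
  cfg <- quiet_config(seed = 1)
  D <- 1
  set.seed(7)
  msd1 <- replicate(1500, {
    tr <- simulate_fbm_track(12, cfg, alpha = 1, A = 4 * D)
    m <- compute_tamsd(tr, 1)
    m$msd[1]
  })
  se <- stats::sd(msd1) / sqrt(length(msd1))
  expect_lt(abs(mean(msd1) - 4 * D * 0.01), 3 * se)
})

test_that("zero-amplitude tracks do not move and bad parameters error", {
  cfg <- quiet_config(seed = 1)
  tr <- simulate_fbm_track(50, cfg, alpha = 0.7, A = 0, seed = 3)
  expect_true(all(tr$x == tr$x[1]) && all(tr$y == tr$y[1]))
  expect_equal(compute_tamsd(tr, 5)$msd, rep(0, 5))
  expect_error(simulate_fbm_track(1, cfg), "n_steps")
  expect_error(simulate_fbm_track(10, cfg, alpha = 2.5), "alpha")
  expect_error(simulate_fbm_track(10, cfg, alpha = 0), "alpha")
})

test_that("localization noise shifts the fitted MSD offset by 4 sigma^2", {
  sigma <- 0.03
  cfg <- sim_config(noise_sigma = sigma, seed = 1)
  set.seed(42)
  trs <- lapply(seq_len(600), function(i)
    simulate_fbm_track(64, cfg, alpha = 1, A = 0.4, track_id = i))
  em <- ensemble_msd(trs, max_lag = 30)
  fit <- fit_anomalous(em)
  expect_equal(fit$sigma^2, 4 * sigma^2, tolerance = 0.25)
  expect_equal(fit$alpha, 1, tolerance = 0.1)
})

test_that("hybrid switching follows the Markov stationary distribution", {
  cfg <- quiet_config(seed = 1)
  # absorbing immobile state: rates (0, .) can never leave state 1
  tr0 <- simulate_hybrid_track(200, cfg, rates = c(0, 0.3), seed = 5)
  expect_true(all(attr(tr0, "states") == 1L))
  # symmetric rates: 50/50 occupancy within binomial CI
  tr1 <- simulate_hybrid_track(4000, cfg, rates = c(0.05, 0.05), seed = 6)
  occ <- mean(attr(tr1, "states") == 2L)
  # correlated samples: effective n ~ n * rate; allow a generous CI
  expect_lt(abs(occ - 0.5), 0.08)
  # asymmetric rates 0.02/0.10: stationary mobile occupancy 1/6
  set.seed(8)
  occ2 <- mean(replicate(60, {
    tr <- simulate_hybrid_track(500, cfg, rates = c(0.02, 0.10))
    mean(attr(tr, "states") == 2L)
  }))
  expect_lt(abs(occ2 - 1 / 6), 0.03)
  expect_error(simulate_hybrid_track(10, cfg, rates = c(1, 0.5)), "rates")
})

test_that("population mixture, track lengths and labels behave as configured", {
  # degenerate mixture
  cfg1 <- sim_config(class_fractions = c(1, 0, 0), n_tracks = 50, seed = 2)
  pop1 <- simulate_population(cfg1)
  expect_true(all(pop1$labels$true_label == "immobile"))
  expect_equal(length(pop1$tracks), 50L)
  # mean track length 17 at survival 15/16, n = 1e4 within 0.5
  cfg2 <- sim_config(n_tracks = 10000, seed = 3)
  lens <- draw_lengths_for_test(cfg2)
  expect_lt(abs(mean(lens) - 17), 0.5)
  # latent process fractions within multinomial 99% CI at n = 1000
  cfg3 <- sim_config(n_tracks = 1000, seed = 4)
  pop3 <- simulate_population(cfg3)
  p <- cfg3$class_fractions
  emp <- table(factor(pop3$labels$process,
                      levels = c("immobile", "hybrid", "mobile"))) / 1000
  z <- stats::qnorm(0.995)
  for (cl in names(p))
    expect_lt(abs(emp[[cl]] - p[[cl]]), z * sqrt(p[[cl]] * (1 - p[[cl]]) / 1000))
  # observational labels only reassign never-switching hybrid tracks
  hy <- pop3$labels[pop3$labels$process == "hybrid", ]
  expect_true(all(pop3$labels$true_label[pop3$labels$process != "hybrid"] ==
                    pop3$labels$process[pop3$labels$process != "hybrid"]))
  expect_true(all(hy$true_label %in% c("immobile", "hybrid", "mobile")))
})

test_that("identical seed and config give bit-identical populations", {
  cfg <- sim_config(n_tracks = 80, seed = 99)
  a <- simulate_population(cfg); b <- simulate_population(cfg)
  expect_identical(as_track_table(a), as_track_table(b))
  expect_identical(a$labels, b$labels)
})

test_that("damage scaling raises inside-ROI immobile jumps and spares the rest", {
  roi <- rect_roi(width = 3, height = 12)
  cfg <- sim_config(n_tracks = 2500, seed = 31)
  ratio <- 1.5
  colls <- simulate_damage_experiment(cfg, roi,
    jump_ratios = c(before = 1, `1min` = ratio))
  js <- lapply(colls, function(cl) {
    lab <- cl$labels
    keep <- lab$track_id[lab$process == "immobile"]
    inside <- lab$track_id[lab$in_roi]
    tt <- as_track_table(cl)
    trs <- as_trajectories(tt)
    list(inside = vapply(trs[intersect(keep, inside)], mean_jump_distance, 0),
         outside = vapply(trs[setdiff(keep, inside)], mean_jump_distance, 0))
  })
  r_in <- mean(js$`1min`$inside) / mean(js$before$inside)
  r_out <- mean(js$`1min`$outside) / mean(js$before$outside)
  expect_equal(r_in, ratio, tolerance = 0.07)
  expect_equal(r_out, 1, tolerance = 0.05)
  # null configuration: before vs before statistically indistinguishable
  t0 <- yuen_welch(js$before$inside, js$before$outside)
  expect_gt(t0$p_value, 0.05)
})

test_that("a non-unit damage profile without an ROI is rejected", {
  cfg <- sim_config(seed = 1, n_tracks = 10)
  expect_error(simulate_damage_experiment(cfg, NULL,
    jump_ratios = c(before = 1, `1min` = 1.5)), "ROI")
})
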