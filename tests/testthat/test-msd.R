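# MSD computation, anomalous-diffusion fitting and effective diffusion.

# independent O(N^2) double-loop oracle for the time-averaged MSD
tamsd_oracle <- function(traj, max_lag) {
  N <- n_points(traj)
  vapply(seq_len(max_lag), function(n) {
    acc <- 0
    for (i in 1:(N - n))
      acc <- acc + (traj$x[i + n] - traj$x[i])^2 + (traj$y[i + n] - traj$y[i])^2
    acc / (N - n)
  }, 0)
}

test_that("time-averaged MSD matches hand values and the double-loop oracle", {
  tr <- traj_from_xy(c(0, 1, 1), c(0, 0, 1))
  m <- compute_tamsd(tr, 2)
  expect_equal(m$msd, c(1.0, 2.0))
  expect_equal(m$n_pairs, c(2L, 1L))
  expect_equal(m$lag_s, c(0.01, 0.02))
  # oracle equality on random trajectories
  set.seed(4)
  for (rep in 1:5) {
    N <- sample(6:40, 1)
    tr <- traj_from_xy(cumsum(rnorm(N)), cumsum(rnorm(N)))
    expect_equal(compute_tamsd(tr, N - 1L)$msd, tamsd_oracle(tr, N - 1L))
  }
  # constant positions
  trc <- traj_from_xy(rep(2, 10), rep(-1, 10))
  expect_equal(compute_tamsd(trc, 9)$msd, rep(0, 9))
  # ballistic identity: collinear steps of length d give MSD(n dt) = (n d)^2
  d <- 0.3
  trb <- traj_from_xy(d * (0:10), rep(0, 11))
  expect_equal(compute_tamsd(trb, 10)$msd, (d * (1:10))^2)
  expect_warning(compute_tamsd(trb, 50), "truncated")
})

test_that("coordinate scaling by c scales MSD by c^2 exactly", {
  set.seed(9)
  tr <- traj_from_xy(cumsum(rnorm(30)), cumsum(rnorm(30)))
  tr2 <- tr; tr2$x <- 3 * tr$x; tr2$y <- 3 * tr$y
  expect_equal(compute_tamsd(tr2, 29)$msd, 9 * compute_tamsd(tr, 29)$msd)
})

test_that("ensemble MSD averages tracks equally", {
  tr1 <- traj_from_xy(c(0, 1, 2), c(0, 0, 0), id = "a")  # MSD(dt) = 1
  tr3 <- traj_from_xy(c(0, sqrt(3), 2 * sqrt(3)), c(0, 0, 0), id = "b") # 3
  em <- ensemble_msd(list(tr1, tr3), max_lag = 1)
  expect_equal(em$msd, 2.0)
  # identical tracks: ensemble equals the single-track curve
  em2 <- ensemble_msd(list(tr1, tr1, tr1), max_lag = 2)
  expect_equal(em2$msd, compute_tamsd(tr1, 2)$msd)
  expect_error(ensemble_msd(list(), 3), "empty")
})

test_that("ensemble MSD of simulated Brownian tracks matches 4 D t", {
  cfg <- quiet_config(seed = 1)
  set.seed(10)
  trs <- lapply(1:1000, function(i)
    simulate_fbm_track(20, cfg, alpha = 1, A = 4, track_id = i))
  em <- ensemble_msd(trs, max_lag = 5)
  # per-lag SE from per-track spread
  for (l in 1:5) {
    per <- vapply(trs, function(t) compute_tamsd(t, 5)$msd[l], 0)
    se <- sd(per) / sqrt(length(per))
    expect_lt(abs(em$msd[l] - 4 * l * 0.01), 3 * se)
  }
})

test_that("anomalous fit recovers exact generating curves", {
  t <- seq(0.01, 2, by = 0.01)
  mk <- function(values) {
    d <- data.frame(lag_s = t, msd = values, n_pairs = rep(100, length(t)))
    class(d) <- c("msd_curve", "data.frame"); d
  }
  # subdiffusive regime printed for the undamaged locus
  f1 <- fit_anomalous(mk(0.004 * t^0.59))
  expect_equal(f1$A, 0.004, tolerance = 1e-3)
  expect_equal(f1$alpha, 0.59, tolerance = 1e-3)
  expect_lt(f1$sigma, 1e-4)
  expect_gte(f1$r_squared, 0.999)
  # directed regime
  f2 <- fit_anomalous(mk(0.0002 * t^1.9))
  expect_equal(f2$alpha, 1.9, tolerance = 1e-3)
  expect_equal(f2$A, 0.0002, tolerance = 1e-3)
  # Brownian limit with offset
  f3 <- fit_anomalous(mk(4 * 0.1 * t + 0.03^2))
  expect_equal(f3$alpha, 1.0, tolerance = 1e-3)
  expect_equal(f3$A, 0.4, tolerance = 1e-3)
  expect_equal(f3$sigma, 0.03, tolerance = 1e-2)
})

test_that("fit recovery holds across replicate noisy simulations", {
  cfg0 <- quiet_config(seed = 1)
  grid <- expand.grid(alpha = c(0.5, 1.0), A = c(0.04))
  for (g in seq_len(nrow(grid))) {
    set.seed(300 + g)
    alphas <- replicate(10, {
      trs <- lapply(1:150, function(i)
        simulate_fbm_track(64, cfg0, alpha = grid$alpha[g], A = grid$A[g]))
      fit_anomalous(ensemble_msd(trs, 32), fix_sigma_zero = TRUE)$alpha
    })
    expect_lt(abs(median(alphas) - grid$alpha[g]), 0.05)
  }
})

test_that("effective diffusion summaries follow their closed forms", {
  t <- seq(0.01, 1.5, by = 0.01)
  d <- data.frame(lag_s = t, msd = 0.4 * t, n_pairs = rep(50, length(t)))
  class(d) <- c("msd_curve", "data.frame")
  ed <- effective_diffusion(d)
  expect_equal(ed$D_first4, 0.1, tolerance = 1e-10)
  # Brownian: tangent D equals D
  fitb <- list(A = 4 * 0.25, alpha = 1)
  expect_equal(effective_diffusion(d, fitb)$D_tangent, 0.25)
  # subdiffusive closed form vs numerical tangent averaging
  fit <- list(A = 0.004, alpha = 0.59)
  tt <- seq(0.1, 1.0, length.out = 20001)
  numeric_mean <- mean(fit$A * fit$alpha * tt^(fit$alpha - 1)) / 4
  expect_equal(effective_diffusion(d, fit)$D_tangent, numeric_mean,
               tolerance = 1e-4)
})
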