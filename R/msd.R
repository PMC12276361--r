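# Mean squared displacement analysis: per-track time-averaged MSD,
# time-ensemble averaging, the anomalous-diffusion fit
# MSD(t) = A t^alpha + sigma^2, and the two effective-diffusion
# summaries (first-4-point slope / 4, and the tangent of the fitted
# curve averaged over 0.1-1.0 s).

#' Time-averaged MSD of one trajectory
#'
#' For lag n, averages the squared displacement over all `N - n`
#' overlapping pairs:
#' `MSD(n dt) = 1/(N-n) * sum_i [(x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2]`.
#' Assumes consecutive frames (the simulator and standard 100 Hz
#' acquisitions have no gaps); lag is indexed in frames.
#'
#' @param traj A [trajectory()] with at least 2 points.
#' @param max_lag Largest lag in frames (truncated to `N - 1` with a
#'   warning if larger).
#' @return An `msd_curve`: data.frame with columns `lag_s`, `msd`,
#'   `n_pairs`, plus attribute `n_tracks_averaged = 1`.
#' @export
compute_tamsd <- function(traj, max_lag = n_points(traj) - 1L) {
  N <- n_points(traj)
  if (N < 2L) stop("trajectory needs >= 2 points")
  if (max_lag < 1L) stop("max_lag must be >= 1")
  if (max_lag > N - 1L) {
    warning("max_lag exceeds N - 1; truncated")
    max_lag <- N - 1L
  }
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(n) {
    dx <- traj$x[(1L + n):N] - traj$x[1:(N - n)]
    dy <- traj$y[(1L + n):N] - traj$y[1:(N - n)]
    mean(dx * dx + dy * dy)
  }, 0)
  out <- data.frame(lag_s = lags * traj$frame_interval, msd = msd,
                    n_pairs = N - lags)
  attr(out, "n_tracks_averaged") <- 1L
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Time-ensemble-averaged MSD over a set of trajectories
#'
#' Per-lag arithmetic mean of the per-track time-averaged MSDs, weighting
#' tracks equally; lags contributed by fewer than `min_tracks` tracks are
#' dropped. `n_pairs` accumulates the displacement pairs over tracks (used
#' as fit weights).
#'
#' @param trajs List of [trajectory()] (all with the same frame interval).
#' @param max_lag Largest lag in frames.
#' @param min_tracks Minimum number of contributing tracks per lag.
#' @return An `msd_curve` with attribute `n_tracks_averaged`.
#' @export
ensemble_msd <- function(trajs, max_lag, min_tracks = 1L) {
  if (length(trajs) < 1L) stop("empty trajectory collection")
  trajs <- Filter(function(t) n_points(t) >= 2L, trajs)
  if (length(trajs) < 1L) stop("no trajectory with >= 2 points")
  dt <- trajs[[1L]]$frame_interval
  acc_sum <- numeric(max_lag); acc_n <- integer(max_lag)
  acc_pairs <- numeric(max_lag)
  for (tr in trajs) {
    ml <- min(max_lag, n_points(tr) - 1L)
    m <- compute_tamsd(tr, ml)
    idx <- seq_len(ml)
    acc_sum[idx] <- acc_sum[idx] + m$msd
    acc_n[idx] <- acc_n[idx] + 1L
    acc_pairs[idx] <- acc_pairs[idx] + m$n_pairs
  }
  keep <- acc_n >= min_tracks
  out <- data.frame(lag_s = seq_len(max_lag)[keep] * dt,
                    msd = (acc_sum / acc_n)[keep],
                    n_pairs = acc_pairs[keep])
  attr(out, "n_tracks_averaged") <- length(trajs)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the anomalous-diffusion model to an MSD curve
#'
#' Weighted nonlinear least squares of `MSD(t) = A t^alpha + sigma^2`
#' (weights = per-lag pair counts), initialized from a log-log linear
#' regression and solved by Levenberg-Marquardt with `A >= 0`,
#' `0 < alpha <= 2`, `sigma^2 >= 0`. `alpha < 1` indicates subdiffusion,
#' `alpha > 1` a directed component; `sigma` is the static positioning
#' accuracy entering the printed model as a constant `sigma^2` offset.
#'
#' @param msd An `msd_curve`.
#' @param fit_range Length-2 numeric, lag window in seconds (inclusive);
#'   `NULL` fits all lags.
#' @param min_pairs Lags with fewer pairs are excluded (default 5).
#' @param fix_sigma_zero If `TRUE`, constrain the offset to 0.
#' @return An `anomalous_fit`: list with `A`, `alpha`, `sigma`,
#'   `r_squared`, `fit_range`, `converged`, `n_lags`.
#' @export
fit_anomalous <- function(msd, fit_range = NULL, min_pairs = 5L,
                          fix_sigma_zero = FALSE) {
  d <- as.data.frame(msd)
  if (!is.null(fit_range))
    d <- d[d$lag_s >= fit_range[1] & d$lag_s <= fit_range[2], ]
  d <- d[d$n_pairs >= min_pairs & d$msd > 0, ]
  if (nrow(d) < 4L) stop("need >= 4 usable lags in the fit range")
  # log-log initialization ignores the offset
  init <- stats::lm(log(msd) ~ log(lag_s), data = d)
  a0 <- min(max(unname(stats::coef(init)[2]), 0.05), 2)
  A0 <- exp(unname(stats::coef(init)[1]))
  w <- sqrt(d$n_pairs)
  resid_fn <- if (fix_sigma_zero)
    function(p) w * (d$msd - p[1] * d$lag_s^p[2])
  else
    function(p) w * (d$msd - p[1] * d$lag_s^p[2] - p[3])
  start <- if (fix_sigma_zero) c(A0, a0) else c(A0, a0, 0)
  lower <- if (fix_sigma_zero) c(0, 0.01) else c(0, 0.01, 0)
  upper <- if (fix_sigma_zero) c(Inf, 2) else c(Inf, 2, Inf)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- fit$par
  pred <- d$msd - resid_fn(cf) / w
  r2 <- 1 - sum((d$msd - pred)^2) / sum((d$msd - mean(d$msd))^2)
  conv <- fit$info %in% 1:4
  if (!conv)
    warning("anomalous fit did not converge: ", fit$message)
  structure(list(A = cf[1], alpha = cf[2],
                 sigma = if (fix_sigma_zero) 0 else sqrt(cf[3]),
                 r_squared = r2,
                 fit_range = range(d$lag_s), converged = conv,
                 n_lags = nrow(d)),
            class = "anomalous_fit")
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat(sprintf("<anomalous_fit> MSD(t) = %.4g t^%.3f + (%.4g)^2, R2 = %.4f\n",
              x$A, x$alpha, x$sigma, x$r_squared))
  invisible(x)
}

#' Effective diffusion coefficients from an MSD curve and its fit
#'
#' `D_first4` is the slope of the unweighted linear fit of the first four
#' MSD points divided by 4 (with noise it inherits the static offset's
#' short-lag inflation). `D_tangent` is the denoised summary: the tangent
#' of the fitted power law `A t^alpha` averaged over `[t_min, t_max]`
#' seconds, i.e. `A (t_max^alpha - t_min^alpha) / (4 (t_max - t_min))` in
#' closed form (the localization offset does not contribute to the
#' derivative).
#'
#' @param msd An `msd_curve` (needs >= 4 lags for `D_first4`).
#' @param fit An `anomalous_fit` (needed for `D_tangent`).
#' @param t_min,t_max Tangent-averaging window in seconds.
#' @return List with `D_first4` and `D_tangent` (um^2/s; `NA` when
#'   unavailable).
#' @export
effective_diffusion <- function(msd, fit = NULL, t_min = 0.1, t_max = 1.0) {
  d <- as.data.frame(msd)
  D_first4 <- if (nrow(d) >= 4L) {
    p <- unname(stats::coef(stats::lm(msd ~ lag_s, data = d[1:4, ]))[2])
    p / 4
  } else NA_real_
  D_tangent <- if (!is.null(fit))
    effective_d_tangent(fit$A, fit$alpha, t_min, t_max) else NA_real_
  list(D_first4 = D_first4, D_tangent = D_tangent)
}
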