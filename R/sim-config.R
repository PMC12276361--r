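#' Simulation configuration for synthetic single-particle tracking data
#'
#' Bundles every parameter of the synthetic SPT experiment: acquisition
#' geometry (frame interval, pixel size), the three-population mixture
#' (immobile / hybrid / mobile), per-population motion parameters,
#' localization noise, geometric track-length attrition, and the
#' damage-response scaling applied to immobile-class steps inside the
#' irradiated region of interest.
#'
#' Defaults encode the acquisition and population structure of a 100 Hz
#' photoactivation SPT experiment on core histones: 160 nm pixels, 10 ms
#' frames, population fractions 84/7/9% (immobile/hybrid/mobile), mean
#' track length 17 frames from out-of-focus attrition, mobile diffusion
#' coefficient 3.661 um^2/s, and a subdiffusive (alpha = 0.5,
#' Rouse-like) immobile class whose amplitude is calibrated so that the
#' pre-damage immobile mean 10-ms jump distance is ~0.063 um at the
#' default 30 nm localization error.
#'
#' @param frame_interval Frame interval in seconds.
#' @param pixel_size Pixel size in micrometres.
#' @param class_fractions Named or unnamed length-3 non-negative vector of
#'   mixture proportions over (immobile, hybrid, mobile); must sum to 1.
#' @param immobile_alpha Anomalous MSD exponent of the immobile class,
#'   in (0, 2].
#' @param immobile_A Anomalous coefficient of the immobile class in
#'   um^2/s^alpha (2-D convention: MSD(t) = A t^alpha).
#' @param mobile_D Diffusion coefficient of the mobile (Brownian) class in
#'   um^2/s.
#' @param hybrid_switch_rates Length-2 vector of per-frame switching
#'   probabilities (immobile -> mobile, mobile -> immobile), each in (0, 1)
#'   for `simulate_population()`.
#' @param hybrid_min_dwell Minimum consecutive frames a state must last
#'   to count as visited when deriving the observational track label
#'   (an HMM-smoothed segment classifier cannot resolve shorter
#'   flickers); hybrid requires both states sustained.
#' @param noise_sigma Localization error (standard deviation per
#'   coordinate) in micrometres, added i.i.d. to true positions.
#' @param track_survival_p Per-frame survival probability after the second
#'   point; track length is 2 + Geometric, so the mean length is
#'   `2 + p/(1-p)` frames (p = 15/16 gives 17).
#' @param n_tracks Number of tracks to simulate.
#' @param damage_effect Multiplicative factor applied to immobile-class
#'   step amplitudes inside the ROI (1 = no damage).
#' @param field_size Side of the square nuclear field (um) over which
#'   track origins are scattered.
#' @param seed Integer seed; mandatory for reproducible fixtures.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(frame_interval = 0.01,
                       pixel_size = 0.160,
                       class_fractions = c(immobile = 0.84, hybrid = 0.07, mobile = 0.09),
                       immobile_alpha = 0.5,
                       immobile_A = 0.013,
                       mobile_D = 3.661,
                       hybrid_switch_rates = c(0.1, 0.1),
                       hybrid_min_dwell = 5L,
                       noise_sigma = 0.03,
                       track_survival_p = 15 / 16,
                       n_tracks = 1000L,
                       damage_effect = 1,
                       field_size = 12,
                       seed = 1L) {
  cfg <- list(
    frame_interval = frame_interval, pixel_size = pixel_size,
    class_fractions = stats::setNames(as.numeric(class_fractions),
                                      c("immobile", "hybrid", "mobile")),
    immobile_alpha = immobile_alpha, immobile_A = immobile_A,
    mobile_D = mobile_D,
    hybrid_switch_rates = as.numeric(hybrid_switch_rates),
    hybrid_min_dwell = as.integer(hybrid_min_dwell),
    noise_sigma = noise_sigma, track_survival_p = track_survival_p,
    n_tracks = as.integer(n_tracks), damage_effect = damage_effect,
    field_size = field_size, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  f <- cfg$class_fractions
  if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("class_fractions must be 3 non-negative proportions summing to 1")
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (cfg$track_survival_p <= 0 || cfg$track_survival_p > 1)
    stop("track_survival_p must be in (0, 1]")
  if (cfg$immobile_alpha <= 0 || cfg$immobile_alpha > 2)
    stop("immobile_alpha must be in (0, 2]")
  if (cfg$immobile_A < 0 || cfg$mobile_D <= 0)
    stop("immobile_A must be >= 0 and mobile_D > 0")
  # classifier separability assumption: mobile D at least 10x the immobile
  # effective (tangent) diffusion coefficient
  d_imm <- effective_d_tangent(cfg$immobile_A, cfg$immobile_alpha)
  if (cfg$immobile_A > 0 && cfg$mobile_D < 10 * d_imm)
    stop("mobile_D must exceed the immobile effective D by >= 10x")
  if (cfg$n_tracks < 1L) stop("n_tracks must be >= 1")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  frame_interval: %g s, pixel_size: %g um\n",
              x$frame_interval, x$pixel_size))
  cat(sprintf("  fractions (imm/hyb/mob): %s\n",
              paste(signif(x$class_fractions, 3), collapse = "/")))
  cat(sprintf("  immobile: A=%g um^2/s^%g; mobile: D=%g um^2/s\n",
              x$immobile_A, x$immobile_alpha, x$mobile_D))
  cat(sprintf("  noise %g um, survival p=%g (mean length %g), n=%d, seed=%d\n",
              x$noise_sigma, x$track_survival_p,
              2 + x$track_survival_p / (1 - x$track_survival_p),
              x$n_tracks, x$seed))
  invisible(x)
}

# closed-form mean tangent of A t^alpha over [0.1, 1.0] s divided by 4
# (the denoised effective diffusion coefficient summary)
effective_d_tangent <- function(A, alpha, t_min = 0.1, t_max = 1.0) {
  A * (t_max^alpha - t_min^alpha) / (4 * (t_max - t_min))
}
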