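# Synthetic single-particle-tracking data: exact fractional Brownian
# tracks, two-state hybrid tracks, population mixtures and the simulated
# micro-irradiation (damage) experiment.

#' Exact fractional Gaussian noise by circulant embedding
#'
#' Generates `n` increments of unit-time-variance fractional Gaussian
#' noise with Hurst exponent `H` by the Davies-Harte circulant-embedding
#' construction (exact covariance). For short series, or if the circulant
#' eigenvalues are not all non-negative, falls back to a Cholesky
#' factorization of the exact covariance matrix (also exact).
#'
#' Consumes `2*(n+1)` standard normal draws from the current RNG stream in
#' the circulant branch and `n` in the Cholesky branch.
#'
#' @param n Number of increments.
#' @param H Hurst exponent in (0, 1].
#' @return Numeric vector of length `n` with `Var(sum(fgn[1:k])) = k^(2H)`.
#' @keywords internal
fgn_exact <- function(n, H) {
  stopifnot(n >= 1, H > 0, H <= 1)
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  if (n >= 8) {
    m <- 2L * n
    circ <- c(g[1:(n + 1)], g[n:2])          # length 2n
    lam <- Re(stats::fft(circ))
    if (all(lam > -1e-8 * max(lam))) {
      lam <- pmax(lam, 0)
      z <- stats::rnorm(m + 2L)              # fixed draw count for determinism
      w <- complex(length.out = m)
      w[1L] <- sqrt(lam[1L] / m) * z[1L]
      w[n + 1L] <- sqrt(lam[n + 1L] / m) * z[2L]
      a <- z[seq(3L, by = 2L, length.out = n - 1L)]
      b <- z[seq(4L, by = 2L, length.out = n - 1L)]
      idx <- 2:n
      w[idx] <- sqrt(lam[idx] / (2 * m)) * complex(real = a, imaginary = b)
      w[m + 2L - idx] <- Conj(w[idx])
      return(Re(stats::fft(w))[1:n])
    }
  }
  # exact covariance Cholesky fallback
  sig <- matrix(g[abs(outer(1:n, 1:n, "-")) + 1L], n, n)
  L <- chol(sig)
  as.numeric(crossprod(L, stats::rnorm(n)))
}

# per-axis fBm increments over n_steps-1 frames with 2-D MSD(t) = A t^alpha
# (each axis contributes A/2 t^alpha); dt in seconds
fbm_increments <- function(n_inc, alpha, A, dt) {
  if (A == 0) return(numeric(n_inc))
  sc <- sqrt((A / 2) * dt^alpha)
  sc * fgn_exact(n_inc, H = alpha / 2)
}

#' Simulate one fractional-Brownian-motion trajectory
#'
#' The x and y increments are independent exact fBm increments, each
#' contributing `A/2 * t^alpha` to the 2-D ensemble MSD, so the noise-free
#' ensemble MSD is `A * t^alpha`; i.i.d. Gaussian localization noise of
#' standard deviation `cfg$noise_sigma` per coordinate adds a constant
#' `4 * noise_sigma^2` offset.
#'
#' @param n_steps Number of localizations (>= 2).
#' @param cfg A [sim_config()] (frame interval, localization noise).
#' @param alpha Anomalous exponent in (0, 2]; `alpha = 1` is Brownian
#'   motion with `A = 4 D`.
#' @param A Anomalous coefficient in um^2/s^alpha.
#' @param seed Optional integer seed (sets the RNG before drawing).
#' @param track_id Identifier for the returned trajectory.
#' @param origin Length-2 numeric, starting position in um.
#' @return A [trajectory()].
#' @export
simulate_fbm_track <- function(n_steps, cfg, alpha = cfg$immobile_alpha,
                               A = cfg$immobile_A, seed = NULL,
                               track_id = "fbm", origin = c(0, 0)) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (alpha <= 0 || alpha > 2) stop("alpha must be in (0, 2]")
  if (A < 0) stop("A must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dt <- cfg$frame_interval
  dx <- fbm_increments(n_steps - 1L, alpha, A, dt)
  dy <- fbm_increments(n_steps - 1L, alpha, A, dt)
  x <- origin[1] + cumsum(c(0, dx))
  y <- origin[2] + cumsum(c(0, dy))
  if (cfg$noise_sigma > 0) {
    x <- x + stats::rnorm(n_steps, 0, cfg$noise_sigma)
    y <- y + stats::rnorm(n_steps, 0, cfg$noise_sigma)
  }
  trajectory(track_id, 0:(n_steps - 1L), x, y, dt)
}

#' Simulate one two-state (hybrid) trajectory
#'
#' Per-frame Markov switching between an immobile phase, whose steps are
#' drawn from the fBm immobile generator, and a mobile phase with Brownian
#' steps at `cfg$mobile_D`. The initial state is drawn from the chain's
#' stationary distribution. The realized per-frame state sequence is
#' attached as attribute `"states"` (1 = immobile, 2 = mobile) for oracle
#' tests and observational labelling.
#'
#' @inheritParams simulate_fbm_track
#' @param rates Length-2 per-frame switch probabilities
#'   (immobile -> mobile, mobile -> immobile), each in `[0, 1)`.
#' @return A [trajectory()] with attribute `"states"`.
#' @export
simulate_hybrid_track <- function(n_steps, cfg,
                                  rates = cfg$hybrid_switch_rates,
                                  seed = NULL, track_id = "hybrid",
                                  origin = c(0, 0)) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (any(rates < 0) || any(rates >= 1))
    stop("switch rates must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  dt <- cfg$frame_interval
  p12 <- rates[1]; p21 <- rates[2]
  states <- integer(n_steps)
  states[1L] <- if (p12 + p21 == 0) 1L else
    if (stats::runif(1) < p12 / (p12 + p21)) 2L else 1L
  if (n_steps > 1L) {
    u <- stats::runif(n_steps - 1L)
    for (i in 2:n_steps) {
      states[i] <- if (states[i - 1L] == 1L) {
        if (u[i - 1L] < p12) 2L else 1L
      } else {
        if (u[i - 1L] < p21) 1L else 2L
      }
    }
  }
  n_inc <- n_steps - 1L
  imm_dx <- fbm_increments(n_inc, cfg$immobile_alpha, cfg$immobile_A, dt)
  imm_dy <- fbm_increments(n_inc, cfg$immobile_alpha, cfg$immobile_A, dt)
  sd_mob <- sqrt(2 * cfg$mobile_D * dt)
  mob_dx <- stats::rnorm(n_inc, 0, sd_mob)
  mob_dy <- stats::rnorm(n_inc, 0, sd_mob)
  mob <- states[1:n_inc] == 2L          # state at the step's start frame
  dx <- ifelse(mob, mob_dx, imm_dx)
  dy <- ifelse(mob, mob_dy, imm_dy)
  x <- origin[1] + cumsum(c(0, dx))
  y <- origin[2] + cumsum(c(0, dy))
  if (cfg$noise_sigma > 0) {
    x <- x + stats::rnorm(n_steps, 0, cfg$noise_sigma)
    y <- y + stats::rnorm(n_steps, 0, cfg$noise_sigma)
  }
  tr <- trajectory(track_id, 0:(n_steps - 1L), x, y, dt)
  attr(tr, "states") <- states
  tr
}

# geometric track-length model: 2 obligatory points then per-frame
# survival with probability p (out-of-focus attrition)
draw_track_lengths <- function(n, survival_p) {
  2L + stats::rgeom(n, prob = 1 - survival_p)
}


# Observational class of a realized two-state sequence: a state counts
# as visited only if it is sustained for at least min_dwell consecutive
# frames (an HMM-smoothed segment classifier cannot resolve shorter
# flickers); hybrid requires both states sustained, otherwise the track
# is labelled by its dominant (or only) sustained state.
observational_label <- function(states, min_dwell = 5L) {
  r <- rle(states)
  sustained <- unique(r$values[r$lengths >= min_dwell])
  if (length(sustained) == 2L) return("hybrid")
  if (length(sustained) == 1L)
    return(c("immobile", "mobile")[sustained])
  dom <- if (sum(states == 1L) >= sum(states == 2L)) 1L else 2L
  c("immobile", "mobile")[dom]
}

#' Simulate a labelled track population
#'
#' Draws each track's population (immobile / hybrid / mobile) from
#' `cfg$class_fractions`, its length from the geometric attrition model
#' (mean `2 + p/(1-p)` frames), scatters origins uniformly over the square
#' nuclear field, and adds i.i.d. localization noise. When
#' `cfg$damage_effect != 1`, the immobile-state step amplitudes of tracks
#' whose time-averaged centroid falls inside `roi` (pure immobile tracks
#' and the immobile phases of hybrid tracks; localization noise and
#' mobile-phase statistics are unaffected) are multiplied by the factor;
#' an ROI is then required.
#'
#' Ground-truth labels are observational: a hybrid-process track whose
#' realized state sequence never switches is labelled by the single state
#' it displayed (the segment-to-track mapping rule used throughout the
#' classification analyses); the latent generating process is reported in
#' the `process` column.
#'
#' @param cfg A [sim_config()]; `cfg$seed` seeds the simulation.
#' @param roi A [rect_roi()] or `NULL`.
#' @return A `track_collection`: list with `tracks` (list of
#'   [trajectory()]), `labels` (data.frame: track_id, true_label, process,
#'   n_points, in_roi), `roi`, `config`.
#' @export
simulate_population <- function(cfg, roi = NULL) {
  validate_sim_config(cfg)
  if (cfg$damage_effect != 1 && is.null(roi))
    stop("damage_effect != 1 requires an ROI")
  set.seed(cfg$seed)
  n <- cfg$n_tracks
  procs <- sample(c("immobile", "hybrid", "mobile"), n, replace = TRUE,
                  prob = cfg$class_fractions)
  lens <- draw_track_lengths(n, cfg$track_survival_p)
  half <- cfg$field_size / 2
  ox <- stats::runif(n, -half, half)
  oy <- stats::runif(n, -half, half)
  tracks <- vector("list", n)
  true_label <- character(n)
  in_roi <- logical(n)
  dt <- cfg$frame_interval
  for (i in seq_len(n)) {
    id <- sprintf("t%05d", i)
    tr <- switch(procs[i],
      immobile = simulate_fbm_track(lens[i], cfg, track_id = id,
                                    origin = c(ox[i], oy[i])),
      mobile = simulate_fbm_track(lens[i], cfg, alpha = 1,
                                  A = 4 * cfg$mobile_D, track_id = id,
                                  origin = c(ox[i], oy[i])),
      hybrid = simulate_hybrid_track(lens[i], cfg, track_id = id,
                                     origin = c(ox[i], oy[i]))
    )
    lab <- procs[i]
    if (lab == "hybrid")
      lab <- observational_label(attr(tr, "states"), cfg$hybrid_min_dwell)
    inside <- !is.null(roi) && roi_contains(roi, mean(tr$x), mean(tr$y))
    if (cfg$damage_effect != 1 && inside && procs[i] != "mobile") {
      # damage amplifies chromatin-bound motion: re-draw the track with
      # the immobile-state step amplitude scaled (hybrid tracks keep
      # their mobile-phase statistics untouched)
      cfg_d <- cfg
      cfg_d$immobile_A <- cfg$immobile_A * cfg$damage_effect^2
      tr <- switch(procs[i],
        immobile = simulate_fbm_track(lens[i], cfg_d, track_id = id,
                                      origin = c(ox[i], oy[i])),
        hybrid = simulate_hybrid_track(lens[i], cfg_d, track_id = id,
                                       origin = c(ox[i], oy[i]))
      )
      if (procs[i] == "hybrid")
        lab <- observational_label(attr(tr, "states"), cfg$hybrid_min_dwell)
      inside <- roi_contains(roi, mean(tr$x), mean(tr$y))
    }
    tracks[[i]] <- tr
    true_label[i] <- lab
    in_roi[i] <- inside
  }
  structure(
    list(tracks = tracks,
         labels = data.frame(track_id = track_ids(tracks),
                             true_label = true_label, process = procs,
                             n_points = lens, in_roi = in_roi,
                             stringsAsFactors = FALSE),
         roi = roi, config = cfg),
    class = "track_collection"
  )
}

#' @export
print.track_collection <- function(x, ...) {
  cat(sprintf("<track_collection: %d tracks>\n", length(x$tracks)))
  print(table(x$labels$true_label))
  invisible(x)
}

#' Amplitude factor producing a target mean-jump-distance ratio
#'
#' The observed one-frame jump of an immobile track is the modulus of a
#' 2-D Gaussian whose per-axis variance is `s^2 + 2 sigma_n^2`, where
#' `s^2 = (A/2) dt^alpha` is the true per-axis step variance and `sigma_n`
#' the localization error. The mean jump therefore scales with the square
#' root of that total variance, and reproducing a programmed mean-jump
#' ratio r requires scaling the true step amplitude by
#' `f = sqrt((r^2 (s^2 + 2 sigma_n^2) - 2 sigma_n^2) / s^2)`.
#'
#' @param ratio Target mean jump-distance ratio (>= observable floor set
#'   by the noise).
#' @param cfg A [sim_config()].
#' @return The multiplicative step-amplitude factor.
#' @export
damage_factor_for_jump_ratio <- function(ratio, cfg) {
  s2 <- (cfg$immobile_A / 2) * cfg$frame_interval^cfg$immobile_alpha
  n2 <- 2 * cfg$noise_sigma^2
  f2 <- (ratio^2 * (s2 + n2) - n2) / s2
  if (f2 <= 0)
    stop("requested ratio below the localization-noise floor")
  sqrt(f2)
}

#' Simulate the micro-irradiation time course
#'
#' Emits one labelled track collection per timepoint. The damage response
#' is a multiplicative, time-dependent scaling of immobile-class step
#' amplitudes restricted to tracks inside the ROI; outside-ROI tracks are
#' statistically identical across timepoints. The per-timepoint amplitude
#' factors are derived from the programmed mean-jump-distance ratios via
#' [damage_factor_for_jump_ratio()].
#'
#' @param cfg A [sim_config()].
#' @param roi A [rect_roi()] (required when any ratio differs from 1).
#' @param jump_ratios Named numeric vector of programmed mean-jump ratios
#'   per timepoint, relative to `before`. The default encodes a transient
#'   ~50% surge at 1 min with recovery by 5 min and a mild drop below
#'   baseline at 10 min.
#' @return Named list of `track_collection`, one per timepoint.
#' @export
simulate_damage_experiment <- function(cfg, roi,
                                       jump_ratios = c(before = 1, `1min` = 1.5,
                                                       `5min` = 1.0, `10min` = 0.9)) {
  if (any(jump_ratios != 1) && is.null(roi))
    stop("a non-unit damage profile requires an ROI")
  out <- vector("list", length(jump_ratios))
  names(out) <- names(jump_ratios)
  for (k in seq_along(jump_ratios)) {
    cfg_k <- cfg
    cfg_k$seed <- (cfg$seed + 97003L * k) %% .Machine$integer.max
    r <- jump_ratios[[k]]
    cfg_k$damage_effect <- if (r == 1) 1 else damage_factor_for_jump_ratio(r, cfg)
    out[[k]] <- simulate_population(cfg_k, roi = roi)
  }
  out
}

#' Simulate a class-balanced labelled training set
#'
#' Draws `n_per_class` tracks per observational class at the generator's
#' study conditions, with geometric lengths conditioned on the minimum
#' length required for classification. Hybrid tracks are drawn from the
#' two-state process conditioned on both phases being sustained (a track
#' that merely flickers is, observationally, not a hybrid track).
#'
#' An annotated training corpus from a micro-irradiation experiment
#' pools imaging sequences acquired before and after damage, so its
#' immobile class spans the damage-amplified step-amplitude range; to
#' emulate that provenance, a fraction `amplitude_fraction` of the
#' immobile examples receives a step-amplitude factor drawn uniformly
#' from `amplitude_range` (labels unchanged). Set the fraction to 0 for
#' a purely pre-damage corpus.
#'
#' @param n_per_class Tracks per class.
#' @param cfg A [sim_config()]; `cfg$seed` seeds the draw.
#' @param min_points Minimum localizations per track (default 5).
#' @param amplitude_range Range of the uniform step-amplitude factor
#'   applied to a subset of immobile examples.
#' @param amplitude_fraction Fraction of immobile examples amplified.
#' @return A `track_collection` with balanced `true_label`.
#' @export
simulate_training_set <- function(n_per_class, cfg = sim_config(),
                                  min_points = 5L,
                                  amplitude_range = c(1, 2.5),
                                  amplitude_fraction = 0.5) {
  set.seed(cfg$seed)
  draw_len <- function() {
    repeat {
      l <- draw_track_lengths(1L, cfg$track_survival_p)
      if (l >= min_points) return(l)
    }
  }
  tracks <- list(); labs <- character(0)
  i <- 0L
  for (cl in c("immobile", "hybrid", "mobile")) {
    made <- 0L
    while (made < n_per_class) {
      i <- i + 1L
      id <- sprintf("t%05d", i)
      l <- draw_len()
      tr <- switch(cl,
        immobile = {
          f <- if (stats::runif(1) < amplitude_fraction)
            stats::runif(1, amplitude_range[1], amplitude_range[2]) else 1
          simulate_fbm_track(l, cfg, A = cfg$immobile_A * f^2, track_id = id)
        },
        mobile = simulate_fbm_track(l, cfg, alpha = 1,
                                    A = 4 * cfg$mobile_D, track_id = id),
        hybrid = simulate_hybrid_track(l, cfg, track_id = id)
      )
      if (cl == "hybrid" &&
          observational_label(attr(tr, "states"),
                              cfg$hybrid_min_dwell) != "hybrid")
        next  # not observationally hybrid
      made <- made + 1L
      tracks[[length(tracks) + 1L]] <- tr
      labs <- c(labs, cl)
    }
  }
  structure(
    list(tracks = tracks,
         labels = data.frame(track_id = track_ids(tracks),
                             true_label = labs, process = labs,
                             n_points = vapply(tracks, n_points, 0L),
                             in_roi = NA, stringsAsFactors = FALSE),
         roi = NULL, config = cfg),
    class = "track_collection"
  )
}
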