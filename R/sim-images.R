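# Synthetic photoactivated-line image series: a bright band of
# programmed thickness with Gaussian-PSF-convolved edges over uniform
# background, corrupted by Poisson shot noise and Gaussian read noise.

#' Image simulation configuration
#'
#' @param image_shape Length-2 integer (rows, cols) in pixels.
#' @param pixel_size Pixel size (um).
#' @param line_width_profile Numeric vector: band thickness (um) per
#'   timepoint; its length sets the number of frames.
#' @param line_center Band centre (um, along rows); default mid-image.
#' @param psf_sigma Gaussian PSF standard deviation (um), >= 0.
#' @param intensity_fg,intensity_bg Foreground / background mean
#'   intensities (photon counts for the Poisson model).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts);
#'   set `poisson = FALSE` and `read_noise_sd = 0` for noise-free frames.
#' @param poisson Apply Poisson shot noise.
#' @param frame_interval_s Seconds between frames.
#' @param irradiation_frame Index of the first post-irradiation frame.
#' @param seed Integer seed.
#' @return An `image_sim_config` list.
#' @export
image_sim_config <- function(image_shape = c(128L, 128L), pixel_size = 0.1,
                             line_width_profile = rep(1.0, 10),
                             line_center = NULL, psf_sigma = 0.15,
                             intensity_fg = 1000, intensity_bg = 100,
                             read_noise_sd = 5, poisson = TRUE,
                             frame_interval_s = 10, irradiation_frame = 1L,
                             seed = 1L) {
  if (any(line_width_profile <= 0)) stop("line_width_profile must be positive")
  if (psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (max(line_width_profile) >= image_shape[1] * pixel_size)
    stop("line thicker than the image")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 line_width_profile = line_width_profile,
                 line_center = line_center %||%
                   (image_shape[1] * pixel_size / 2),
                 psf_sigma = psf_sigma, intensity_fg = intensity_fg,
                 intensity_bg = intensity_bg, read_noise_sd = read_noise_sd,
                 poisson = poisson, frame_interval_s = frame_interval_s,
                 irradiation_frame = as.integer(irradiation_frame),
                 seed = as.integer(seed)),
            class = "image_sim_config")
}

#' Simulate a photoactivated-line image series
#'
#' Each frame holds a horizontal band of the programmed thickness whose
#' edge profile is the exact Gaussian-PSF convolution of a hard band
#' (difference of normal CDFs along the row coordinate), scaled between
#' background and foreground intensity; Poisson shot noise and Gaussian
#' read noise are then applied per pixel. The programmed thickness per
#' frame is retained as ground truth.
#'
#' @param cfg An [image_sim_config()].
#' @return A `nucleus_image_series`: list with `frames` (list of
#'   matrices), `pixel_size`, `timestamps`, `irradiation_frame`, and
#'   `truth` (data.frame: frame, width_um).
#' @export
simulate_line_images <- function(cfg) {
  set.seed(cfg$seed)
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  yc <- (seq_len(nr) - 0.5) * cfg$pixel_size   # pixel-centre row coords (um)
  frames <- vector("list", length(cfg$line_width_profile))
  for (f in seq_along(cfg$line_width_profile)) {
    w <- cfg$line_width_profile[f]
    lo <- cfg$line_center - w / 2; hi <- cfg$line_center + w / 2
    prof <- if (cfg$psf_sigma > 0) {
      stats::pnorm((yc - lo) / cfg$psf_sigma) -
        stats::pnorm((yc - hi) / cfg$psf_sigma)
    } else as.numeric(yc >= lo & yc <= hi)
    mean_img <- matrix(cfg$intensity_bg +
                         (cfg$intensity_fg - cfg$intensity_bg) * prof,
                       nrow = nr, ncol = nc)
    img <- if (cfg$poisson)
      matrix(stats::rpois(nr * nc, mean_img), nr, nc) else mean_img
    if (cfg$read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$read_noise_sd), nr, nc)
    frames[[f]] <- img
  }
  structure(list(frames = frames, pixel_size = cfg$pixel_size,
                 timestamps = (seq_along(frames) - 1L) * cfg$frame_interval_s,
                 irradiation_frame = cfg$irradiation_frame,
                 truth = data.frame(frame = seq_along(frames),
                                    width_um = cfg$line_width_profile)),
            class = "nucleus_image_series")
}

#' @export
print.nucleus_image_series <- function(x, ...) {
  cat(sprintf("<nucleus_image_series: %d frames of %d x %d px (%g um/px)>\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size))
  invisible(x)
}

#' Write / read an image series as multi-page TIFF
#'
#' Frames are rescaled to [0, 1] by `scale` for the 16-bit container.
#' Requires the suggested \pkg{tiff} package.
#'
#' @param series A `nucleus_image_series`.
#' @param path TIFF path.
#' @param scale Intensity divisor applied before writing.
#' @return `read_image_series` returns a `nucleus_image_series`.
#' @export
write_image_series <- function(series, path, scale = 2^16 - 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  tiff::writeTIFF(lapply(series$frames, function(f)
    pmin(pmax(f / scale, 0), 1)), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_series
#' @param pixel_size,frame_interval_s,irradiation_frame Metadata for the
#'   returned series.
#' @export
read_image_series <- function(path, pixel_size, frame_interval_s = 10,
                              irradiation_frame = 1L, scale = 2^16 - 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f) f * scale)
  structure(list(frames = frames, pixel_size = pixel_size,
                 timestamps = (seq_along(frames) - 1L) * frame_interval_s,
                 irradiation_frame = as.integer(irradiation_frame),
                 truth = NULL),
            class = "nucleus_image_series")
}
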