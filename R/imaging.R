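# Chromatin-compaction quantification from photoactivated-line image
# series (k-means segmentation + moment-equivalent ellipse minor axis)
# and protein recruitment kinetics (background-subtracted,
# photobleaching-corrected ROI intensity).

#' Segment the photoactivated line by k-means thresholding
#'
#' Clusters pixel intensities into `k` groups (deterministic
#' quantile-based initialization), takes the highest-mean cluster as
#' foreground, and retains its largest 8-connected component to suppress
#' speckle. A frame whose foreground/background separation is weaker
#' than the within-cluster spread is flagged unsegmentable.
#'
#' @param frame Numeric matrix of intensities (non-zero variance).
#' @param k Number of clusters (default 2).
#' @return Logical mask with attribute `unsegmentable`.
#' @export
segment_line <- function(frame, k = 2L) {
  v <- as.numeric(frame)
  if (stats::sd(v) == 0) stop("frame has zero variance")
  init <- stats::quantile(v, probs = seq(0, 1, length.out = k + 2L)[2:(k + 1L)])
  init <- unique(as.numeric(init))
  if (length(init) < k) init <- seq(min(v), max(v), length.out = k)
  km <- stats::kmeans(v, centers = init, iter.max = 50L)
  fg_cluster <- which.max(km$centers)
  mask <- matrix(km$cluster == fg_cluster, nrow(frame), ncol(frame))
  # separation check: distance between the two top cluster centres vs
  # the pooled within-cluster spread (a unimodal frame splits into two
  # adjacent clusters less than ~3 within-sd apart)
  ord <- order(km$centers, decreasing = TRUE)
  sep <- km$centers[ord[1]] - km$centers[ord[2]]
  within_sd <- sqrt(km$tot.withinss / length(v))
  unseg <- !is.finite(sep) || (within_sd > 0 && sep < 4 * within_sd)
  if (unseg) {
    warning("weak foreground/background separation; frame flagged unsegmentable")
    attr(mask, "unsegmentable") <- TRUE
    return(mask)
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labv <- as.integer(EBImage::imageData(lab))
  labv_pos <- labv[labv > 0L]
  if (length(labv_pos) == 0L) {
    attr(mask, "unsegmentable") <- TRUE
    warning("empty foreground; frame flagged unsegmentable")
    return(mask)
  }
  biggest <- as.integer(names(which.max(table(labv_pos))))
  mask <- matrix(labv == biggest, nrow(frame), ncol(frame))
  attr(mask, "unsegmentable") <- FALSE
  mask
}

#' Line thickness from a segmentation mask
#'
#' Minor axis of the ellipse sharing the mask's second central moments.
#' Pixels are treated as unit squares (their 1/12 extent variance is
#' added to the pixel-centre scatter), so a solid axis-aligned rectangle
#' of height h recovers the continuous-rectangle identity
#' `minor axis = 4 sqrt(h^2/12) = 2 h / sqrt(3)` exactly. The estimate is
#' invariant under mask rotation.
#'
#' @param mask Logical matrix.
#' @param pixel_size Pixel size (um).
#' @return Minor-axis length in um (`NA` with a warning for masks of
#'   fewer than 5 pixels).
#' @export
thickness_from_mask <- function(mask, pixel_size = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  if (nrow(idx) < 5L) {
    warning("mask smaller than 5 pixels; thickness flagged")
    return(NA_real_)
  }
  xy <- cbind(idx[, 2], idx[, 1])   # x = col, y = row (pixel centres)
  cc <- sweep(xy, 2, colMeans(xy))
  S <- crossprod(cc) / nrow(cc) + diag(1 / 12, 2)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  4 * sqrt(min(ev)) * pixel_size
}

#' Normalized line-thickness time series
#'
#' Per-frame k-means segmentation and moment-ellipse minor axis,
#' normalized to a reference frame — by default the first
#' post-irradiation frame (`series$irradiation_frame`), i.e. the
#' compaction state immediately after damage induction. Unsegmentable
#' frames are reported as `NA`, never interpolated.
#'
#' @param series A `nucleus_image_series`.
#' @param reference_frame Frame index used for normalization.
#' @param k k-means cluster count.
#' @return Data.frame `frame`, `time_s`, `thickness_um`, `normalized`.
#' @export
thickness_series <- function(series, reference_frame = series$irradiation_frame,
                             k = 2L) {
  th <- vapply(series$frames, function(fr) {
    m <- tryCatch(segment_line(fr, k), warning = function(w) NULL,
                  error = function(e) NULL)
    if (is.null(m) || isTRUE(attr(m, "unsegmentable"))) return(NA_real_)
    thickness_from_mask(m, series$pixel_size)
  }, 0)
  if (is.na(th[reference_frame]))
    stop("reference frame is not segmentable")
  data.frame(frame = seq_along(th), time_s = series$timestamps,
             thickness_um = th, normalized = th / th[reference_frame])
}

#' Protein recruitment curve at the irradiated region
#'
#' Per frame computes
#' `(mean over ROI - mean over background) / (mean over nucleus - mean
#' over background)` — dividing by the nuclear signal cancels imaging
#' photobleaching — and then normalizes by the mean of that ratio over
#' the pre-damage frames, so the pre-damage level is 1 by construction.
#'
#' @param series A `nucleus_image_series`.
#' @param roi_mask,nucleus_mask,background_mask Logical masks (background
#'   must lie outside the nucleus).
#' @param predamage_frames Integer indices of pre-damage frames (>= 1).
#' @return Data.frame `frame`, `time_s`, `recruitment` (frames with a
#'   vanishing denominator are `NA` with a warning).
#' @export
recruitment_curve <- function(series, roi_mask, nucleus_mask, background_mask,
                              predamage_frames) {
  if (length(predamage_frames) < 1L) stop("need >= 1 pre-damage frame")
  if (any(background_mask & nucleus_mask))
    stop("background mask must lie outside the nucleus mask")
  ratio <- vapply(series$frames, function(fr) {
    bg <- mean(fr[background_mask])
    den <- mean(fr[nucleus_mask]) - bg
    if (!is.finite(den) || den == 0) return(NA_real_)
    (mean(fr[roi_mask]) - bg) / den
  }, 0)
  if (anyNA(ratio)) warning("frames with vanishing nuclear signal flagged NA")
  base <- mean(ratio[predamage_frames])
  data.frame(frame = seq_along(ratio), time_s = series$timestamps,
             recruitment = ratio / base)
}
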