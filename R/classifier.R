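# Trajectory classification (HTC): rasterization of trajectories to
# diffusion-colored images, coordinate-level rotation augmentation, the
# 5-conv-layer CNN with its training loop, and the segment-threshold
# baseline implementing the segment-to-track mapping rule.

#' Instantaneous diffusion coefficient of one displacement
#'
#' Standard 2-D single-step estimator `(dx^2 + dy^2) / (4 dt)`.
#'
#' @param dx,dy Displacement components (um); vectorized.
#' @param dt Time interval (s), > 0.
#' @return Instantaneous D in um^2/s.
#' @export
instantaneous_diffusion <- function(dx, dy, dt) {
  if (any(dt <= 0)) stop("dt must be > 0")
  (dx * dx + dy * dy) / (4 * dt)
}

#' Rendering configuration
#'
#' @param image_size Canvas side in pixels (512 in the full-scale
#'   configuration; reducible for desk-scale runs, >= 96).
#' @param d_thresholds Increasing positive pair (um^2/s) partitioning the
#'   instantaneous D into the red / green / blue channels: red <= first,
#'   first < green <= second, blue > second (boundaries belong to the
#'   lower-named channel).
#' @param window_um Physical width (um) mapped across the canvas.
#' @param step_px Sub-pixel marching step for anti-aliased segments.
#' @param auto_expand Grow (never shrink) the window to the track's
#'   bounding box, so no part of a large track is lost; with `FALSE`
#'   out-of-window portions are clipped with a warning.
#' @return A `render_config` list.
#' @export
render_config <- function(image_size = 512L, d_thresholds = c(0.5, 1.0),
                          window_um = 2, step_px = 0.4, auto_expand = TRUE) {
  if (length(d_thresholds) != 2L || d_thresholds[1] <= 0 ||
      d_thresholds[2] <= d_thresholds[1])
    stop("d_thresholds must be strictly increasing and positive")
  structure(list(image_size = as.integer(image_size),
                 d_thresholds = as.numeric(d_thresholds),
                 window_um = window_um, step_px = step_px,
                 auto_expand = auto_expand),
            class = "render_config")
}

# per-segment channel (1 red, 2 green, 3 blue) from instantaneous D
segment_channels <- function(traj, d_thresholds = c(0.5, 1.0)) {
  n <- n_points(traj)
  if (n < 2L) return(integer(0))
  dt <- diff(traj$frames) * traj$frame_interval
  D <- instantaneous_diffusion(diff(traj$x), diff(traj$y), dt)
  # boundary values belong to the lower-named channel; tolerate float
  # round-off so that a displacement engineered to sit on a threshold
  # does not spill into the next channel
  tol <- 1 + 1e-9
  ifelse(D <= d_thresholds[1] * tol, 1L, ifelse(D <= d_thresholds[2] * tol, 2L, 3L))
}

#' Coordinate-level rotation augmentation
#'
#' Returns `n_rotations` rotated copies of a standardized trajectory, the
#' k-th rotated about the origin by `k * 2 pi / (n_rotations + 1)` radians
#' (15 degree increments for the default 23, completing a uniform 24-fold
#' orbit with the original). Rotations act on coordinates before
#' rasterization, preserving all pairwise distances exactly, hence every
#' copy has the identical instantaneous-D sequence and segment colors.
#'
#' @param traj A standardized [trajectory()].
#' @param n_rotations Number of non-identity rotations (default 23).
#' @return List of rotated trajectories.
#' @export
augment_rotations <- function(traj, n_rotations = 23L) {
  if (n_rotations < 0L) stop("n_rotations must be >= 0")
  step <- 2 * pi / (n_rotations + 1)
  lapply(seq_len(n_rotations), function(k) rotate_trajectory(traj, k * step))
}

#' Render a trajectory as a diffusion-colored image
#'
#' Standardizes the trajectory, then draws each consecutive-position pair
#' as an anti-aliased straight segment at sub-pixel precision into the
#' single channel selected by its instantaneous diffusion coefficient.
#' The canvas is centred on the track's bounding box (the physical scale
#' stays fixed at `window_um` across the canvas), so a track that
#' wanders away from its first localization keeps its full structure in
#' view; portions still exceeding the window are clipped with a warning.
#'
#' @param traj A [trajectory()].
#' @param cfg A [render_config()].
#' @param warn_clip Emit a warning when part of the track falls outside
#'   the canvas.
#' @return `image_size x image_size x 3` array of intensities in [0, 1].
#' @export
render <- function(traj, cfg = render_config(), warn_clip = TRUE) {
  traj <- standardize(traj)
  if (n_points(traj) < 2L) {
    warning(sprintf("track %s: single point, blank rendering", traj$track_id))
    return(array(0, c(cfg$image_size, cfg$image_size, 3L)))
  }
  ch <- segment_channels(traj, cfg$d_thresholds)
  img <- render_traj_cpp(cbind(traj$x, traj$y), ch, cfg$image_size,
                         cfg$window_um, cfg$step_px,
                         isTRUE(cfg$auto_expand))
  if (warn_clip && attr(img, "n_clipped") > 0)
    warning(sprintf("track %s: portions outside the %g um canvas were clipped",
                    traj$track_id, cfg$window_um))
  img
}

#' Training configuration for the CNN
#'
#' @param learning_rate Adam learning rate (default 0.0005).
#' @param batch_size Mini-batch size (default 16).
#' @param n_rotations Non-identity rotation augmentations per track.
#' @param split Training fraction of the shuffled augmented images
#'   (default 0.8; the split is applied after augmentation).
#' @param epochs Maximum passes over the training images.
#' @param image_size Canvas side (default 512; reduce for desk-scale).
#' @param seed Seed for shuffling, weight init and batch order.
#' @param eval_every Batches between validation-subsample evaluations.
#' @param val_subsample Images drawn from the validation split for the
#'   periodic evaluations (the final accuracy always uses the full split).
#' @param early_stop_acc Stop when the evaluation accuracy reaches this
#'   level (plateau detection; `NULL` disables).
#' @param max_batches Hard cap on training batches (`Inf` = epochs only).
#' @param window_um Physical rendering window (um).
#' @param lr_patience,lr_factor Plateau schedule for the optimizer: when
#'   the periodic evaluation accuracy fails to improve for `lr_patience`
#'   consecutive evaluations the learning rate is multiplied by
#'   `lr_factor` (set `lr_patience = Inf` for a constant rate). The
#'   initial rate is always `learning_rate`.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 16L,
                         n_rotations = 23L, split = 0.8, epochs = 2L,
                         image_size = 512L, seed = 1L,
                         eval_every = 100L, val_subsample = 512L,
                         early_stop_acc = 0.995, max_batches = Inf,
                         window_um = 2, lr_patience = 3L, lr_factor = 0.5) {
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)")
  if (n_rotations < 0) stop("n_rotations must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_rotations = as.integer(n_rotations), split = split,
                 epochs = as.integer(epochs),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 eval_every = as.integer(eval_every),
                 val_subsample = as.integer(val_subsample),
                 early_stop_acc = early_stop_acc, max_batches = max_batches,
                 window_um = window_um, lr_patience = lr_patience,
                 lr_factor = lr_factor),
            class = "train_config")
}

#' Build an untrained HTC model
#'
#' Five convolutional layers (8x8-32, 5x5-64, 2x2-128, 2x2-256,
#' 2x2-512), each followed by 2x2 max pooling and batch normalization
#' with ReLU; an adaptive 3x3 max pool, flatten (4,608) and a dense
#' 3-way softmax head. At any admissible input size the trainable
#' parameter count is 762,275 (746,464 convolutional + 1,984 batch-norm
#' affine + 13,827 head).
#'
#' @param cfg A [train_config()] (image size, seed).
#' @param render_cfg A [render_config()]; stored with the model so that
#'   inference can never mismatch the training rendering.
#' @return An `htc_model` (untrained).
#' @export
build_model <- function(cfg = train_config(),
                        render_cfg = render_config(image_size = cfg$image_size,
                                                   window_um = cfg$window_um)) {
  if (render_cfg$image_size != cfg$image_size)
    stop("render and training image sizes differ")
  ptr <- htc_create(cfg$image_size, cfg$seed)
  m <- list(state = htc_get_state(ptr), render = render_cfg,
            train_cfg = cfg, classes = c("immobile", "hybrid", "mobile"),
            history = NULL, val_accuracy = NA_real_, trained = FALSE,
            version = "htc-1")
  m$env <- new.env(parent = emptyenv())
  m$env$ptr <- ptr
  class(m) <- "htc_model"
  m
}

#' Number of trainable parameters
#' @param model An `htc_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) as.integer(htc_nparams(model_ptr(model)))

model_ptr <- function(model) {
  if (is.null(model$env) || is.null(model$env$ptr)) {
    env <- new.env(parent = emptyenv())
    env$ptr <- htc_from_state(model$state)
    # note: cannot persist env into the caller's copy; return fresh ptr
    return(env$ptr)
  }
  model$env$ptr
}

#' @export
print.htc_model <- function(x, ...) {
  cat(sprintf("<htc_model: image_size %d, %s, params %d, val acc %s>\n",
              x$train_cfg$image_size,
              if (x$trained) "trained" else "untrained",
              as.integer(htc_nparams(model_ptr(x))),
              if (is.na(x$val_accuracy)) "NA"
              else sprintf("%.3f", x$val_accuracy)))
  invisible(x)
}

# assemble a rendered batch for a list of (track, rotation) items
render_batch <- function(items, tracks, channels, cfg, render_cfg) {
  S <- render_cfg$image_size
  B <- nrow(items)
  arr <- array(0, c(S, S, 3L, B))
  step <- 2 * pi / (cfg$n_rotations + 1)
  for (b in seq_len(B)) {
    i <- items$track[b]
    tr <- tracks[[i]]
    th <- items$rot[b] * step
    xy <- if (th == 0) cbind(tr$x, tr$y) else {
      co <- cos(th); si <- sin(th)
      cbind(tr$x * co - tr$y * si, tr$x * si + tr$y * co)
    }
    arr[, , , b] <- render_traj_cpp(xy, channels[[i]], S,
                                    render_cfg$window_um, render_cfg$step_px,
                                    isTRUE(render_cfg$auto_expand))
  }
  arr
}

predict_items <- function(ptr, items, tracks, channels, cfg, render_cfg,
                          chunk = 32L) {
  n <- nrow(items)
  pred <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    arr <- render_batch(items[idx, , drop = FALSE], tracks, channels,
                        cfg, render_cfg)
    p <- htc_predict(ptr, arr)
    pred[idx] <- max.col(p, ties.method = "first")
  }
  pred
}

#' Train the HTC classifier
#'
#' Standardizes every track, augments it with coordinate-level rotations,
#' shuffles the augmented image set and splits it 80/20 into training and
#' validation, then optimizes the CNN with Adam on cross-entropy at the
#' configured learning rate and batch size. Images are rasterized on the
#' fly per mini-batch (rotation leaves segment colors untouched, so
#' per-track colors are computed once). The model snapshot with the best
#' periodic validation accuracy is retained, and the returned accuracy is
#' always measured on the full validation split.
#'
#' Training consumes R's RNG (shuffling) and the C++ weight
#' initialization, both seeded from `cfg$seed`; given a fixed seed and
#' thread count the run is reproducible, but accuracy on re-generated
#' data remains stochastic.
#'
#' @param collection A `track_collection` with `true_label`s (at least
#'   two classes), or a list of trajectories plus `labels`.
#' @param cfg A [train_config()].
#' @param labels Optional character vector of labels parallel to the
#'   track list (unused when `collection` is a `track_collection`).
#' @param min_points Minimum localizations per track (default 5).
#' @param verbose Print progress lines.
#' @return A trained `htc_model` with `history` (data.frame of batch,
#'   loss, eval accuracy) and `val_accuracy` (full validation split).
#' @export
train_classifier <- function(collection, cfg = train_config(), labels = NULL,
                             min_points = 5L, verbose = FALSE) {
  if (inherits(collection, "track_collection")) {
    tracks <- collection$tracks
    labels <- collection$labels$true_label
  } else tracks <- collection
  stopifnot(length(tracks) == length(labels))
  keep <- vapply(tracks, n_points, 0L) >= min_points
  tracks <- tracks[keep]; labels <- labels[keep]
  classes <- c("immobile", "hybrid", "mobile")
  y <- match(labels, classes) - 1L
  if (length(unique(y)) < 2L)
    stop("training requires at least two classes")
  render_cfg <- render_config(image_size = cfg$image_size,
                              window_um = cfg$window_um)
  tracks <- lapply(tracks, standardize)
  channels <- lapply(tracks, segment_channels, d_thresholds = render_cfg$d_thresholds)
  # augmented item table: original (rot 0) + n_rotations rotated copies
  n_tr <- length(tracks)
  items <- data.frame(
    track = rep(seq_len(n_tr), each = cfg$n_rotations + 1L),
    rot = rep(0:cfg$n_rotations, times = n_tr)
  )
  items$y <- y[items$track]
  set.seed(cfg$seed)
  items <- items[sample.int(nrow(items)), ]
  n_train <- floor(cfg$split * nrow(items))
  train_items <- items[seq_len(n_train), ]
  val_items <- items[(n_train + 1L):nrow(items), ]
  ptr <- htc_create(cfg$image_size, cfg$seed)
  bs <- cfg$batch_size
  batches_per_epoch <- floor(n_train / bs)
  total_batches <- min(cfg$epochs * batches_per_epoch, cfg$max_batches)
  eval_idx <- sample.int(nrow(val_items), min(cfg$val_subsample, nrow(val_items)))
  best <- list(acc = -1, state = NULL)
  hist <- list()
  lr <- cfg$learning_rate
  stall <- 0L
  b <- 0L; stop_now <- FALSE
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_train)
    for (k in seq_len(batches_per_epoch)) {
      b <- b + 1L
      if (b > total_batches) { stop_now <- TRUE; break }
      sel <- train_items[ord[((k - 1L) * bs + 1L):(k * bs)], ]
      arr <- render_batch(sel, tracks, channels, cfg, render_cfg)
      loss <- htc_train_batch(ptr, arr, sel$y, lr)
      if (b %% cfg$eval_every == 0L || b == total_batches) {
        sub <- val_items[eval_idx, , drop = FALSE]
        pred <- predict_items(ptr, sub, tracks, channels, cfg, render_cfg)
        acc <- mean(pred - 1L == sub$y)
        hist[[length(hist) + 1L]] <- data.frame(batch = b, loss = loss,
                                                eval_accuracy = acc,
                                                learning_rate = lr)
        if (verbose)
          message(sprintf("batch %d: loss %.4f, eval acc %.4f", b, loss, acc))
        if (acc > best$acc) {
          best <- list(acc = acc, state = htc_get_state(ptr))
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (!is.null(cfg$lr_patience) && stall >= cfg$lr_patience) {
            lr <- max(lr * cfg$lr_factor, 1e-6)
            stall <- 0L
            if (verbose) message(sprintf("plateau: learning rate -> %g", lr))
          }
        }
        if (!is.null(cfg$early_stop_acc) && acc >= cfg$early_stop_acc) {
          stop_now <- TRUE; break
        }
      }
    }
    if (stop_now) break
  }
  if (is.null(best$state)) best$state <- htc_get_state(ptr)
  ptr_best <- htc_from_state(best$state)
  pred <- predict_items(ptr_best, val_items, tracks, channels, cfg, render_cfg)
  val_acc <- mean(pred - 1L == val_items$y)
  m <- list(state = best$state, render = render_cfg, train_cfg = cfg,
            classes = classes, history = do.call(rbind, hist),
            val_accuracy = val_acc, trained = TRUE, version = "htc-1",
            n_train = nrow(train_items), n_val = nrow(val_items))
  m$env <- new.env(parent = emptyenv())
  m$env$ptr <- ptr_best
  class(m) <- "htc_model"
  m
}

#' Classify a trajectory with a trained model
#'
#' Standardize, render, forward pass; returns the argmax label and the
#' softmax class probabilities. A blank rendering (single-point track) is
#' reported as unclassifiable.
#'
#' @param model A trained `htc_model`.
#' @param traj A [trajectory()] or list of trajectories.
#' @return A data.frame with `track_id`, `label`, `p_immobile`,
#'   `p_hybrid`, `p_mobile` (`label = NA` for unclassifiable tracks).
#' @export
classify <- function(model, traj) {
  trs <- if (inherits(traj, "trajectory")) list(traj) else traj
  ptr <- model_ptr(model)
  rc <- model$render
  S <- rc$image_size
  n <- length(trs)
  out <- data.frame(track_id = track_ids(trs),
                    label = NA_character_, p_immobile = NA_real_,
                    p_hybrid = NA_real_, p_mobile = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- vapply(trs, n_points, 0L) >= 2L
  if (sum(!ok) > 0)
    message(sprintf("classify: %d unclassifiable single-point track(s)", sum(!ok)))
  idx <- which(ok)
  chunk <- 32L
  for (s in seq(1L, length(idx), by = chunk)) {
    ii <- idx[s:min(length(idx), s + chunk - 1L)]
    arr <- array(0, c(S, S, 3L, length(ii)))
    for (j in seq_along(ii)) {
      tr <- standardize(trs[[ii[j]]])
      ch <- segment_channels(tr, rc$d_thresholds)
      arr[, , , j] <- render_traj_cpp(cbind(tr$x, tr$y), ch, S,
                                      rc$window_um, rc$step_px,
                                      isTRUE(rc$auto_expand))
    }
    p <- htc_predict(ptr, arr)
    out$label[ii] <- model$classes[max.col(p, ties.method = "first")]
    out$p_immobile[ii] <- p[, 1]; out$p_hybrid[ii] <- p[, 2]
    out$p_mobile[ii] <- p[, 3]
  }
  out
}

#' Save / load a trained model
#'
#' The serialized object embeds the rendering configuration and a version
#' stamp so inference cannot mismatch the training rendering.
#'
#' @param model An `htc_model`.
#' @param path File path.
#' @return `load_htc_model` returns the `htc_model`.
#' @export
save_htc_model <- function(model, path) {
  model$env <- NULL
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_htc_model
#' @export
load_htc_model <- function(path) {
  m <- readRDS(path)
  m$env <- new.env(parent = emptyenv())
  m$env$ptr <- htc_from_state(m$state)
  m
}

#' Segment-threshold baseline classifier
#'
#' Two-state reduction of the per-segment instantaneous diffusion
#' coefficient followed by the segment-to-track mapping rule: a track is
#' immobile if every segment is immobile, mobile if every segment is
#' mobile, and hybrid otherwise. Segments are assigned by thresholding
#' the instantaneous D at `threshold` (collapsing the green and blue
#' rendering ranges into "mobile"). Because the single-step D estimate
#' of a Gaussian walk is exponentially distributed, a raw per-segment
#' rule misfires on long tracks; state excursions are therefore accepted
#' with hysteresis -- a run of threshold crossings counts only if it
#' spans at least `min_run` segments, and a mobile run additionally
#' requires one unambiguous segment above `d_hi` (chosen so that a
#' single such step is >10x more likely under the mobile state than
#' under even damage-amplified chromatin motion). Shorter or
#' unsupported excursions merge into the nearest accepted run -- the
#' sticky regularization a segmental HMM would otherwise provide. Set
#' `min_run = 1` for the raw per-segment rule.
#'
#' @param traj A [trajectory()] with >= 2 points.
#' @param threshold Immobile/mobile boundary in um^2/s (default 0.5).
#' @param min_run Minimum accepted run length in segments (default 3).
#' @param d_hi Evidence threshold (um^2/s) a mobile run must exceed at
#'   least once (default 1.5).
#' @return List with `label` and one-hot `probabilities`.
#' @export
baseline_classify_segments <- function(traj, threshold = 0.5,
                                       min_run = 3L, d_hi = 1.5) {
  if (n_points(traj) < 2L) stop("trajectory needs >= 2 points")
  dt <- diff(traj$frames) * traj$frame_interval
  D <- instantaneous_diffusion(diff(traj$x), diff(traj$y), dt)
  mobile <- D > threshold
  if (min_run > 1L && length(D) >= 2L) {
    r <- rle(mobile)
    v <- r$values
    pos <- cumsum(c(1L, utils::head(r$lengths, -1L)))
    for (i in seq_along(v)) {
      if (r$lengths[i] < min_run) { v[i] <- NA; next }
      if (v[i]) {
        seg <- D[pos[i]:(pos[i] + r$lengths[i] - 1L)]
        if (max(seg) <= d_hi) v[i] <- NA
      }
    }
    if (all(is.na(v))) {
      mobile <- rep(mean(mobile) > 0.5, length(mobile))
    } else {
      ok <- which(!is.na(v))
      for (i in seq_along(v)) if (is.na(v[i]))
        v[i] <- v[ok[which.min(abs(ok - i))]]
      mobile <- rep(v, r$lengths)
    }
  }
  label <- if (all(!mobile)) "immobile" else if (all(mobile)) "mobile" else "hybrid"
  probs <- stats::setNames(as.numeric(c("immobile", "hybrid", "mobile") == label),
                           c("immobile", "hybrid", "mobile"))
  list(label = label, probabilities = probs)
}

#' Classify every track in a collection or table with the baseline
#'
#' @param tracks A `track_collection`, `track_table`, or list of
#'   trajectories.
#' @param threshold,min_run,d_hi Passed to
#'   [baseline_classify_segments()].
#' @param min_points Minimum localizations per track.
#' @return Data.frame with `track_id` and `label`.
#' @export
baseline_classify <- function(tracks, threshold = 0.5, min_run = 3L,
                              d_hi = 1.5,
                              min_points = 5L) {
  trs <- if (inherits(tracks, "track_collection")) tracks$tracks
  else if (inherits(tracks, "track_table")) as_trajectories(tracks)
  else tracks
  trs <- trs[vapply(trs, n_points, 0L) >= min_points]
  data.frame(
    track_id = track_ids(trs),
    label = vapply(trs, function(t)
      baseline_classify_segments(t, threshold, min_run, d_hi)$label, ""),
    stringsAsFactors = FALSE
  )
}
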