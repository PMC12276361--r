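# Shared fixtures. The trained CNN is expensive, so it is built once per
# test session and reused by every test that needs it.

.fixtures <- new.env(parent = emptyenv())

# a tiny deterministic trajectory from explicit coordinates
traj_from_xy <- function(x, y, dt = 0.01, frames = seq_along(x) - 1L,
                         id = "fix") {
  trajectory(id, frames, x, y, dt)
}

# noise-free config for closed-form checks
quiet_config <- function(...) {
  sim_config(noise_sigma = 0, ...)
}

# scaled-down study-condition CNN: >= 300 tracks per class at generator
# defaults, 23 rotations, lr 0.0005, batch 16, 128 px canvas, 80/20
# split after augmentation
get_trained_model <- function() {
  if (!is.null(.fixtures$model)) return(.fixtures$model)
  cfg <- sim_config(seed = 20260101L)
  tset <- simulate_training_set(400L, cfg)
  tc <- train_config(image_size = 128L, n_rotations = 23L, epochs = 2L,
                     seed = 42L, eval_every = 100L, val_subsample = 768L,
                     early_stop_acc = 0.99, max_batches = 1250L)
  .fixtures$model <- train_classifier(tset, tc)
  .fixtures$train_set <- tset
  .fixtures$model
}

get_training_set <- function() {
  get_trained_model()
  .fixtures$train_set
}

draw_lengths_for_test <- function(cfg) {
  set.seed(cfg$seed)
  nucleodyn:::draw_track_lengths(cfg$n_tracks, cfg$track_survival_p)
}

run_experiment_core_for_test <- function(tables, labels, roi, n_resamples) {
  nucleodyn:::run_experiment_core(tables, labels, roi, classifier = "truth",
    model = NULL, min_points = 5L, n_resamples = n_resamples, trim = 0.2,
    out_dir = NULL, settings = list(classifier = "labels"))
}
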