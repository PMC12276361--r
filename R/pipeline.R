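# End-to-end orchestration of the synthetic micro-irradiation
# experiment: simulate -> filter -> classify -> per-class jump
# statistics -> condition comparisons -> report.

#' Run the synthetic micro-irradiation experiment
#'
#' Simulates one labelled track collection per timepoint with the
#' programmed inside-ROI jump-ratio profile, filters tracks by length,
#' partitions them by ROI membership (centroid rule), classifies them
#' (segment-threshold baseline by default, or a trained CNN), restricts
#' jump statistics to the immobile class, and compares every
#' post-damage timepoint against "before" inside and outside the ROI.
#' Significance uses two reporting bands: p < 0.001 significant,
#' p > 0.05 not significant. All randomness derives from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param roi A [rect_roi()].
#' @param jump_ratios Programmed per-timepoint mean-jump ratios (first
#'   entry must be the reference condition "before").
#' @param classifier "baseline", "cnn" or "truth" (use simulator labels).
#' @param model Trained [build_model()] object (required for "cnn").
#' @param min_points Minimum track length for classification and jump
#'   statistics.
#' @param n_resamples,trim Bootstrap and Yuen-Welch settings.
#' @param out_dir Optional directory; when given, per-timepoint track
#'   tables, jump summaries, KDE tables and the report JSON are written.
#' @return An `experiment_report`: list with `class_proportions`,
#'   `comparisons` (data.frame), `jump_summaries`, `kdes`, `settings`.
#' @export
run_synthetic_experiment <- function(cfg, roi = rect_roi(),
                                     jump_ratios = c(before = 1, `1min` = 1.5,
                                                     `5min` = 1.0, `10min` = 0.9),
                                     classifier = c("baseline", "cnn", "truth"),
                                     model = NULL, min_points = 5L,
                                     n_resamples = 10000L, trim = 0.2,
                                     out_dir = NULL) {
  classifier <- match.arg(classifier)
  collections <- simulate_damage_experiment(cfg, roi, jump_ratios)
  tables <- lapply(collections, as_track_table)
  run_experiment_core(tables, lapply(collections, `[[`, "labels"),
                      roi = roi, classifier = classifier, model = model,
                      min_points = min_points, n_resamples = n_resamples,
                      trim = trim, out_dir = out_dir,
                      settings = list(jump_ratios = jump_ratios,
                                      seed = cfg$seed, config = unclass(cfg)))
}

#' Run the analysis chain on user-supplied data
#'
#' Entry point for externally produced track tables (and, optionally,
#' image series). Tracks are analysed with the same chain as
#' [run_synthetic_experiment()]; the first timepoint is the reference.
#' When no labels are given a classifier must be supplied: a trained
#' `model`, or `classifier = "baseline"` chosen explicitly.
#'
#' @param tracks Named list of `track_table` (one per timepoint; first =
#'   reference), or `NULL` when only images are analysed.
#' @param labels Optional named list of data.frames (`track_id`,
#'   `true_label` or `label`) parallel to `tracks`.
#' @param images Optional `nucleus_image_series` for thickness analysis.
#' @param roi A [rect_roi()] (required with tracks).
#' @param classifier,model,min_points,n_resamples,trim,out_dir As in
#'   [run_synthetic_experiment()].
#' @return An `experiment_report`; with images supplied it contains a
#'   `thickness` data.frame, and with tracks absent the jump sections are
#'   marked absent.
#' @export
run_analysis <- function(tracks = NULL, labels = NULL, images = NULL,
                         roi = NULL,
                         classifier = c("labels", "cnn", "baseline"),
                         model = NULL, min_points = 5L,
                         n_resamples = 10000L, trim = 0.2, out_dir = NULL) {
  classifier <- match.arg(classifier)
  if (is.null(tracks) && is.null(images))
    stop("supply track tables, an image series, or both")
  rep_tracks <- NULL
  if (!is.null(tracks)) {
    if (is.null(roi)) stop("track analysis requires an ROI")
    if (classifier == "labels" && is.null(labels)) {
      if (!is.null(model)) classifier <- "cnn"
      else stop("no labels supplied: provide per-track labels or a trained model")
    }
    if (classifier == "cnn" && is.null(model))
      stop("classifier = 'cnn' requires a trained model")
    rep_tracks <- run_experiment_core(
      tables = tracks, labels = labels, roi = roi,
      classifier = if (classifier == "labels") "truth" else classifier,
      model = model, min_points = min_points, n_resamples = n_resamples,
      trim = trim, out_dir = out_dir,
      settings = list(classifier = classifier))
  }
  if (!is.null(images)) {
    th <- thickness_series(images)
    if (is.null(rep_tracks)) {
      rep_tracks <- structure(list(class_proportions = NULL, comparisons = NULL,
                                   jump_summaries = NULL, kdes = NULL,
                                   settings = list(), thickness = th),
                              class = "experiment_report")
    } else rep_tracks$thickness <- th
    if (!is.null(out_dir))
      utils::write.csv(th, file.path(out_dir, "thickness_series.csv"),
                       row.names = FALSE)
  }
  rep_tracks
}

run_experiment_core <- function(tables, labels, roi, classifier, model,
                                min_points, n_resamples, trim, out_dir,
                                settings) {
  tps <- names(tables)
  if (is.null(tps) || any(!nzchar(tps)))
    tps <- names(tables) <- paste0("tp", seq_along(tables))
  ref <- tps[1]
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  jump <- list(); props <- list(); kdes <- list()
  for (tp in tps) {
    tab <- filter_by_length(tables[[tp]], min_points)
    cls <- switch(classifier,
      truth = {
        lb <- labels[[tp]]
        names(lb)[names(lb) == "true_label"] <- "label"
        lb[, c("track_id", "label")]
      },
      baseline = baseline_classify(tab, min_points = min_points),
      cnn = {
        cl <- classify(model, as_trajectories(tab))
        cl[!is.na(cl$label), c("track_id", "label")]
      })
    cls <- cls[cls$track_id %in% unique(tab$track_id), ]
    props[[tp]] <- prop.table(table(factor(cls$label,
      levels = c("immobile", "hybrid", "mobile"))))
    for (region in c("inside", "outside")) {
      rt <- suppressWarnings(filter_by_roi(tab, roi, region))
      js <- jump_summary(as_trajectories(rt),
                         labels = data.frame(track_id = cls$track_id,
                                             label = cls$label),
                         class = "immobile", min_points = min_points)
      jump[[paste(tp, region, sep = ".")]] <- js
      if (nrow(js) >= 2)
        kdes[[paste(tp, region, sep = ".")]] <- kde_scott(js$mean_jump_um)
      if (!is.null(out_dir))
        utils::write.csv(js, file.path(out_dir,
          sprintf("jumps_%s_%s.csv", tp, region)), row.names = FALSE)
    }
    if (!is.null(out_dir)) write_tracks(tab, file.path(out_dir,
      sprintf("tracks_%s.csv", tp)))
  }
  comp <- list()
  for (tp in setdiff(tps, ref)) {
    for (region in c("inside", "outside")) {
      a <- jump[[paste(ref, region, sep = ".")]]
      b <- jump[[paste(tp, region, sep = ".")]]
      if (is.null(a) || is.null(b) || nrow(a) < 5 || nrow(b) < 5) next
      cc <- compare_conditions(a, b, n_resamples = n_resamples, trim = trim,
                               seed = 7L + match(tp, tps))
      comp[[length(comp) + 1L]] <- data.frame(
        timepoint = tp, region = region, ratio = cc$ratio,
        ci_lo = cc$ratio_ci_95[1], ci_hi = cc$ratio_ci_95[2],
        p_value = cc$test$p_value, significance = cc$significance,
        n_before = nrow(a), n_after = nrow(b))
    }
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else NULL
  report <- structure(
    list(class_proportions = props, comparisons = comparisons,
         jump_summaries = jump, kdes = kdes,
         settings = c(settings, list(classifier = classifier,
                                     min_points = min_points,
                                     n_resamples = n_resamples, trim = trim))),
    class = "experiment_report")
  if (!is.null(out_dir)) {
    payload <- list(class_proportions = lapply(props, as.list),
                    comparisons = comparisons, settings = report$settings)
    jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  if (!is.null(x$comparisons)) {
    cat("comparisons vs reference:\n")
    print(x$comparisons, row.names = FALSE)
  }
  if (!is.null(x$thickness))
    cat(sprintf("thickness series: %d frames\n", nrow(x$thickness)))
  invisible(x)
}
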