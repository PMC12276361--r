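# nucleodyn

Multiscale chromatin dynamics from single-nucleosome tracking and
micro-irradiation imaging.

## The problem

When a laser draws a line of DNA damage through a nucleus, chromatin
around the lesion relaxes within seconds and recondenses over minutes.
Two live-cell readouts capture this at different scales:

* **Single-particle tracking (SPT)** of individual histones (e.g.
  H2B-Halo with a photoactivatable dye) at 100 Hz. Most histones are
  chromatin-incorporated and barely move; a small fraction diffuses
  freely; some tracks switch between the two. Damage transiently
  increases the mobility of the chromatin-bound population inside the
  irradiated band.
* **Photoactivated-line imaging**, where the thickness of a marked
  chromatin stripe reports the compaction state over time, and
  background-corrected intensity ratios report protein recruitment.

`nucleodyn` implements the full analysis chain for both readouts, plus a
synthetic-data generator that emulates the experiments so every stage is
testable against known ground truth, offline.

## What is inside

| Stage | Functions |
|---|---|
| Synthetic tracks (exact fBm, two-state hybrid, population mixtures, damage time course) | `sim_config()`, `simulate_fbm_track()`, `simulate_hybrid_track()`, `simulate_population()`, `simulate_damage_experiment()`, `simulate_training_set()` |
| Track I/O and filtering | `read_tracks()`, `write_tracks()`, `read_tracks_trackmate()`, `rect_roi()`, `filter_by_roi()`, `filter_by_length()` |
| Trajectory classification | `render()`, `augment_rotations()`, `build_model()`, `train_classifier()`, `classify()`, `baseline_classify()` |
| MSD analysis | `compute_tamsd()`, `ensemble_msd()`, `fit_anomalous()`, `effective_diffusion()` |
| Jump statistics | `mean_jump_distance()`, `jump_summary()`, `bootstrap_mean()`, `kde_scott()`, `yuen_welch()`, `compare_conditions()` |
| Line imaging | `simulate_line_images()`, `segment_line()`, `thickness_from_mask()`, `thickness_series()`, `recruitment_curve()` |
| Orchestration | `run_synthetic_experiment()`, `run_analysis()` |

The core statistics, in the field's standard notation:

* Time-averaged MSD of a track with `N` points at lag `n·Δt`:
  `MSD(n·Δt) = 1/(N−n) Σᵢ [(x₍ᵢ₊ₙ₎−xᵢ)² + (y₍ᵢ₊ₙ₎−yᵢ)²]`, ensemble
  curves fitted with the anomalous model `MSD(t) = A·t^α + σ²`
  (α < 1 subdiffusive, α > 1 directed). Effective diffusion is reported
  both as `D = p/4` (slope of the first four MSD points) and as the
  denoised tangent of the fitted curve averaged over 0.1–1.0 s.
* Model-free mobility: the per-track **mean jump distance** over one
  10 ms frame, summarized by 10,000 bootstrap resamples of the
  per-track averages, Scott's-rule kernel densities, and the two-sided
  Yuen–Welch trimmed-mean test between conditions.
* Trajectory classification (immobile / hybrid / mobile) by a
  5-conv-layer CNN (762,275 trainable parameters) on 3-channel images
  in which each displacement is drawn as a straight segment colored by
  its instantaneous diffusion coefficient `r²/(4Δt)`
  (red ≤ 0.5 < green ≤ 1 < blue, in µm²/s), with coordinate-level
  rotation augmentation; plus a segment-threshold baseline implementing
  the all-segments mapping rule.
* Line thickness as the minor axis of the moment-equivalent ellipse of
  the k-means-segmented stripe, normalized to the first
  post-irradiation frame.

## Worked example

Simulate a damage experiment with a programmed +50% mobility surge
inside a 3 µm irradiated band at 1 min, classify tracks with the
baseline, and compare jump distances per region:

```r
library(nucleodyn)

cfg <- sim_config(n_tracks = 2000, seed = 42)
roi <- rect_roi(width = 3, height = 12)
rep <- run_synthetic_experiment(cfg, roi,
  jump_ratios = c(before = 1, `1min` = 1.5, `5min` = 1.0),
  classifier = "baseline", n_resamples = 10000)
rep$comparisons
#>   timepoint  region ratio ci_lo ci_hi  p_value    significance
#> 1      1min  inside  1.51 1.474  1.56 1.52e-98     significant
#> 2      1min outside  1.00 0.986  1.02 1.51e-01 not significant
#> 3      5min  inside  1.01 0.977  1.04 7.78e-01 not significant
#> 4      5min outside  1.01 0.987  1.03 6.73e-01 not significant
```

The programmed surge is recovered inside the band (ratio 1.51, 95% CI
[1.47, 1.56], p < 0.001), is absent outside and has relaxed by 5 min —
the signature the pipeline is designed to detect. The pre-damage
immobile population inside the band:

```r
js <- rep$jump_summaries$before.inside
bootstrap_mean(js$mean_jump_um, 10000, seed = 1)
#> <bootstrap: mean 0.0616, 95% CI [0.0604, 0.0627], B=10000, n=347>
```

i.e. chromatin-bound histones cover ~62 nm per 10 ms before damage,
with the tight bootstrap CI typical of hundreds of tracks per region.

The numbered scripts under `analysis/` run the full workflow
(simulation → classification → MSD → jump statistics → line thickness →
CNN training) and write their tables under `results/`.

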