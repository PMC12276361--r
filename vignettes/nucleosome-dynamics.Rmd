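---
title: "Quantifying multiscale chromatin dynamics from single-nucleosome tracking and micro-irradiation imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multiscale chromatin dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nucleodyn` implements a complete analysis chain for live-cell chromatin
dynamics experiments at the nucleosome scale: single-particle tracking
(SPT) of individual histones at 100 Hz around a laser-micro-irradiated
band, and time-lapse confocal imaging of a photoactivated chromatin
line. Because the primary biological datasets of such experiments are
large and instrument-specific, the package ships a synthetic-data module
that emulates their statistical structure, so that every stage — track
I/O, trajectory classification, mean-squared-displacement (MSD)
analysis, jump-distance statistics and compaction quantification — is
exercised against ground truth. The chain is driven by the numbered
scripts under `analysis/`; all computation lives in package functions.

# The synthetic SPT generator

## Motion models

Three diffusive populations are simulated, mirroring the behaviour of
core histones in a nucleus:

* **Immobile** (chromatin-incorporated): 2-D fractional Brownian motion
  (fBm) with `MSD(t) = A t^alpha`, the phenomenological stand-in for
  Rouse-like polymer dynamics. Each coordinate receives independent
  exact fBm increments contributing `A/2 t^alpha`. Defaults:
  `alpha = 0.5`, `A = 0.013` µm²/s^0.5.
* **Mobile** (nucleoplasmic): Brownian motion with `D = 3.661` µm²/s,
  more than two orders of magnitude above the immobile effective
  diffusion coefficient — the separability assumption the classifier
  relies on, enforced as a config invariant.
* **Hybrid**: a per-frame two-state Markov chain switching between the
  immobile and mobile step generators, started from its stationary
  distribution. Default switch probabilities are 0.1/0.1 per frame
  (mean dwell ten frames). The switching rates and the mobile-phase
  sub-model are fixtures, not literature claims: published SPT
  experiments of this design report the hybrid class only as tracks
  displaying sustained phases of both behaviours, so the default dwell
  time is chosen long enough that a hybrid track's two phases are
  visible within typical track lengths; per-frame flickering would make
  the class observationally ill-defined (see *Labelling*, below).

fBm increments are synthesized by Davies–Harte circulant embedding
(exact covariance; `2(n+1)` normal draws per axis), with an exact
Cholesky fallback for short series or inadmissible circulant
eigenvalues. Exactness matters because the generator doubles as the
oracle for the MSD estimators.

## Acquisition model

Tracks are observed every 10 ms with 160 nm pixels (the coordinates are
kept in µm; pixels enter only in file conversion). Localization error is
i.i.d. Gaussian per coordinate (`noise_sigma = 0.03` µm), adding the
classical constant `4 sigma^2` offset to 2-D MSD curves. Track length is
`2 + Geometric`: after two obligatory localizations each further frame
survives with probability 15/16, giving the observed mean length of 17
frames; attrition models out-of-focus loss, not photobleaching.
Photophysics (blinking, bleaching kinetics), 3-D motion and camera-noise
calibration are out of scope.

## Calibration

The generator cannot simultaneously reproduce two published summaries of
the immobile class — an effective diffusion coefficient of
~0.0078 µm²/s (tangent of the fitted ensemble MSD over 0.1–1.0 s) and a
pre-damage mean 10-ms jump distance of ~0.063 µm — with a single fBm
population at `alpha ≈ 0.5` and non-negative localization noise: the
D-based calibration forces 10-ms steps of ~0.08 µm even at zero noise.
Since every damage comparison in the pipeline is computed from jump
distances, the generator is calibrated once to the jump-distance scale
(`A = 0.013`, `sigma = 0.03` µm gives a mean immobile jump of
~0.063 µm); the resulting tangent-effective D (~1×10⁻³ µm²/s) preserves
the >100-fold separation from the mobile class. This choice was made
once, before the acceptance thresholds were frozen, and is not
revisited.

## Damage response

Micro-irradiation is modelled as a purely multiplicative, time-dependent
scaling of immobile-state step amplitudes — of pure immobile tracks and
of the immobile phases of hybrid tracks alike — restricted to tracks
whose centroid lies inside the rectangular region of interest (ROI;
3 µm wide band); damage raises the motion of chromatin-bound histones
regardless of which track type they sit in, and scaling only the pure
immobile tracks would leave unamplified fast-phase contamination in the
observational immobile class that both dilutes and destabilizes the
measured jump ratio. No mechanism is implied — the published observable is a changed
jump distance. Because the observed jump mixes true motion with
localization noise, reproducing a programmed mean-jump ratio `r`
requires amplifying the true step amplitude by
`f = sqrt((r^2 (s^2 + 2 sigma^2) - 2 sigma^2)/s^2)` with
`s^2 = (A/2) dt^alpha`; `damage_factor_for_jump_ratio()` implements this
closed form, and the default experiment programs ratios
1.0 / 1.5 / 1.0 / 0.9 at before / 1 min / 5 min / 10 min — a transient
~50% surge with recovery and mild over-compaction.

## Labelling

Ground-truth labels are *observational*: a track is labelled hybrid only
when its realized state sequence sustains each state for at least
`hybrid_min_dwell` consecutive frames (default 5); otherwise it is
labelled by its dominant sustained state. This mirrors the
segment-to-track mapping rule used for HMM-based segment classifiers
(all segments immobile ⇒ immobile, all mobile ⇒ mobile, otherwise
hybrid): a sticky-transition HMM essentially never resolves one- or
two-frame flickers, so such tracks are not observably hybrid — to any
classifier, a human annotator included. Labelling flickers as hybrid
would put the balanced-class Bayes error near 10%. The latent process
assignment is reported alongside (`process` column), and the balanced
training-set generator draws hybrid tracks conditioned on sustaining
both phases. Because an annotated corpus from a micro-irradiation
experiment pools sequences acquired before and after damage, the
training-set generator also draws half of its immobile examples with a
step-amplitude factor spread uniformly over 1–2.5 (labels unchanged),
covering the amplitude range the damage model produces; a classifier
trained on pre-damage amplitudes alone misreads amplified immobile
tracks as hybrid and censors the damaged condition downstream.

# Trajectory classification

## Rendering

A track is standardized (first localization subtracted), then each
consecutive-position pair is drawn as an anti-aliased straight segment
on a square canvas (512 px full scale, 2 µm window; both configurable).
The segment's colour channel encodes its instantaneous diffusion
coefficient `D = (dx² + dy²)/(4 dt)`: red for `D ≤ 0.5` µm²/s, green for
`0.5 < D ≤ 1`, blue for `D > 1`, boundaries belonging to the lower-named
channel. Sub-pixel accuracy is retained by marching sample points along
each segment and splatting bilinear weights. The canvas is centred on
the track's bounding box, and by default the window grows (never
shrinks) to the bounding box of a track that exceeds it: anchoring the
window at the first localization would push the immobile phase of a
mobile-start hybrid track off-canvas, and clipping large tracks at a
hard window loses the same structure at the canvas edge — both
measurably cap classification accuracy. The fixed physical scale, and
with it the absolute stroke-length cue, is preserved for every track
that fits; `auto_expand = FALSE` restores a hard window whose
out-of-canvas portions are clipped with a warning.

## Augmentation

Augmentation operates at coordinate level (never on the rasterized
image): 23 rotations in 15° increments complete a uniform 24-fold orbit
with the original. Rotations preserve pairwise distances exactly, hence
the instantaneous-D sequence and segment colours are rotation-invariant
and computed once per track. The 80/20 train/validation split is applied
*after* augmentation and shuffling, so rotated copies of one track can
land on both sides; validation accuracy therefore measures
augmentation-orbit generalization, not track-level generalization — the
cross-method comparison in `analysis/06_train_cnn.R` uses fresh tracks
for an independent check.

## Network

Five convolutional blocks (kernels/filters 8×8–32, 5×5–64, 2×2–128,
2×2–256, 2×2–512), each conv (stride 1, 'same' padding) followed by 2×2
stride-2 max pooling and batch normalization with ReLU; then an adaptive
3×3 max pool, flatten (4,608 features) and a dense 3-way softmax head.
The head is not described in the source architecture beyond its softmax
output; this reconstruction is chosen because it reproduces the printed
762 K trainable parameters exactly (746,464 conv + 1,984 batch-norm
affine + 13,827 head = 762,275), and the adaptive pool makes the count
independent of the input resolution, so desk-scale runs at 128 px train
the identical parameter set. The optimizer is Adam at the stated
initial learning rate 0.0005 with batch size 16 and cross-entropy
loss, with a plateau schedule (the rate halves after three periodic
evaluations without improvement — at a constant rate the late-training
accuracy oscillates several points and never settles); the optimizer
family and schedule are package choices (the original optimizer
citation is unresolvable), exposed in the configuration. The implementation is
single-precision C++ (im2col + BLAS GEMM) written for this package,
since no deep-learning runtime is part of its dependency set.

Training renders mini-batches on the fly (memory stays flat), evaluates
a fixed validation subsample periodically, keeps the best snapshot, and
stops early once the subsample accuracy plateaus at the configured
level; the reported accuracy is always recomputed on the full validation
split. Given one thread and a fixed seed the run is reproducible;
accuracy on re-generated data is stochastic.

## Baseline (segment-threshold mapping rule)

The comparison classifier assigns each segment immobile/mobile by
thresholding its instantaneous D at 0.5 µm²/s (collapsing green and
blue) and applies the same mapping rule as above. Because the
single-step D estimate of a 2-D Gaussian step is exponentially
distributed, a strict all-segments rule would misclassify a fraction
`1 - (1-p)^m` of long immobile tracks even for small per-segment tail
probability `p`; a state switch is therefore accepted only when at
least three consecutive segments cross the threshold (configurable;
shorter excursions merge into the nearest sustained run) — the sticky
behaviour a segmental HMM's transition prior provides. With defaults
this baseline agrees with ground truth at ≈98% on the 84/7/9 population
mixture and censors only a few percent of amplitude-scaled damaged
tracks; it is the cheap default for pipeline runs, the CNN being the
reference method.

# MSD analysis

The per-track time-averaged MSD uses all `N − n` overlapping pairs at
lag `n`; the ensemble curve averages per-track curves with equal track
weights and accumulates pair counts. The anomalous model
`MSD(t) = A t^alpha + sigma^2` is fitted by weighted Levenberg–Marquardt
(weights = pair counts; `A ≥ 0`, `0 < alpha ≤ 2`, `sigma² ≥ 0` free by
default) from a log–log initialization; lags with fewer than 5 pairs are
excluded. The printed model carries the offset as `sigma²` even though
the 2-D static-error convention would be `4 sigma²`; the printed form is
implemented and the convention noted — the simulator's noise `sigma`
therefore reappears in the fit as `sigma_fit ≈ 2 sigma`. Two effective
diffusion summaries are provided: `D_first4` (least-squares slope of the
first four MSD points divided by 4, noise-inflated by construction) and
the denoised `D_tangent`, the tangent of the fitted power law averaged
over 0.1–1.0 s. Its closed form is `A (t1^alpha − t0^alpha)/(4 (t1 −
t0))` — integrating the derivative cancels the exponent prefactor — and
the implementation is cross-checked against numerical tangent averaging
in the tests. Directed regimes (`alpha` up to 2) use the same model;
two-regime fits are handled by the configurable lag window (short
`t < 5 s` vs long), since the original window boundaries are unstated.

# Jump-distance statistics

Histone mobility is summarized model-free as the per-track mean
Euclidean displacement between consecutive frames (10 ms); gaps are
skipped, never divided down, and tracks shorter than 5 localizations are
excluded (configurable — the source experiments state no threshold). By
default only the immobile class enters, matching the focus on
chromatin-incorporated histones. Bootstrap: 10,000 resamples of the
per-track values at original sample size, percentile 95% CIs (the CI
method is unstated in the source; percentile is recorded in the output).
KDEs use a Gaussian kernel with Scott's-rule bandwidth
`sd · n^(−1/5)` and equal weights. Conditions are compared with the
two-sided Yuen–Welch test on 20%-trimmed means with Winsorized variances
and Welch degrees of freedom (trim fraction unstated in the source; 0.2
is the conventional choice and is reported in the output; at trim 0 the
implementation reduces exactly to Welch's t, which the tests verify
against `t.test`). Significance is reported in the two bands used by the
source analyses — `p < 0.001` significant, `p > 0.05` not significant —
with the raw p always attached. No multiple-testing correction is
applied across timepoints.

# Compaction and recruitment imaging

The photoactivated line is segmented per frame by k-means on pixel
intensities (k = 2 by default; the cluster count in the original
routine is unstated) with deterministic quantile initialization,
foreground = highest-mean cluster, largest connected component retained.
Frames whose two top clusters are closer than four pooled within-cluster
standard deviations are flagged unsegmentable (a unimodal frame splits
into two adjacent clusters); flagged frames yield `NA`, never
interpolation. Thickness is the minor axis of the ellipse sharing the
mask's second central moments, `4 sqrt(lambda_min)`; pixels are treated
as unit squares (adding 1/12 to the pixel-centre variance), which makes
the discrete estimate match the continuous rectangle identity
`2 h / sqrt(3)` exactly and keeps the estimator rotation-invariant.
Normalization is to the first post-irradiation frame (the state
immediately after damage induction); normalizing to an arbitrary
reference frame is available where a pre-damage anchor is preferred.
Recruitment curves compute `(ROI − background)/(nucleus − background)`
per frame — the nuclear ratio cancels imaging photobleaching — then
normalize to the pre-damage mean, so the pre-damage level is 1 by
construction. Masks are inputs (the original nuclei were segmented
manually); nucleus auto-segmentation and drift registration are out of
scope. The synthetic line generator draws the band with analytically
PSF-convolved edges (difference of normal CDFs) plus Poisson shot noise
and Gaussian read noise, retaining the programmed width as ground truth.

# Problem sizes, determinism, and what the tests show

The test-suite and acceptance problem sizes are deliberate desk-scale
choices: 320 tracks per class for classifier training at 128 px,
hundreds to a few thousand tracks for population-level checks, 400–1500
replicates for Monte-Carlo oracles, 500 replicate experiments for
bootstrap-coverage calibration. Every random operation takes an explicit
seed, and the pipeline derives per-stage seeds deterministically from a
single root seed, so identical configurations give byte-identical track
tables, images and reports.

Passing tests demonstrate that each estimator recovers what the
generator programmed under the stated noise model. They do not
demonstrate robustness to what the generator omits: tracking errors
(misconnections, identity switches), anisotropic or spatially varying
localization error, nuclear movement and drift, photophysics, 3-D
defocus bias, or chromatin-state heterogeneity. Conclusions about real
data still require the instrument-side controls the original
experimental design includes. The classifier is specific to the motion
regimes it was trained on; transferring it to other proteins or frame
rates requires retraining and revalidation.

# Known limitations

* Validation accuracy is measured on the augmentation-orbit split (as
  in the source protocol); track-level generalization is checked
  separately on fresh tracks and is typically a few points lower.
* The hybrid class definition is observational; extremely short tracks
  carry little evidence and cap attainable accuracy.
* The CNN trains on one CPU core in tens of minutes at 128 px;
  full-scale 512 px training is supported but not exercised by the
  tests.
* `D_first4` on noisy data is offset-inflated by design (it is reported
  alongside the denoised tangent estimate, which is the summary to use).
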