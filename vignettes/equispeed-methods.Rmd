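---
title: "Estimating horse speed from body-mounted IMUs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating horse speed from body-mounted IMUs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Locomotion speed is a central covariate in equine biomechanics — lameness
examination, training load monitoring, gait research. GPS gives speed
directly (via Doppler shift) but fails indoors; inertial measurement
units (IMUs) work anywhere but do not measure speed: naive integration of
acceleration drifts within seconds. A practical alternative is to learn a
regression from windowed IMU signal features to concurrently recorded GPS
speed, and then deploy the IMU alone.

`equispeed` implements that pipeline end to end for a seven-IMU equine
sensor layout — poll, withers, sacrum, and the lateral aspect of each
limb (RF, LF, RH, LH) — with tri-axial accelerometer and gyroscope
channels at 200 Hz and a 5 Hz speed reference, across five gaits (walk,
trot, tölt, pace, canter; the tölt is labelled `tolt` in code and files).
Because no public dataset exists for this layout, the package ships a
synthetic-data generator as a first-class, tested module; every
statistical property of the pipeline is asserted against data with known
ground truth.

## Pipeline

1. **Filter**: each channel is low-pass filtered with a 4th-order
   Butterworth at 30 Hz cutoff. Filtering is applied forward and
   backward (zero phase) so that window centers stay aligned with the
   speed timestamps; the magnitude response is therefore applied twice,
   which the tests verify against the analytic transfer function.
   Reflected end-padding removes edge transients (a constant series
   passes through unchanged).
2. **Window**: one 256-sample window per 5 Hz speed sample, centered on
   the IMU sample nearest the speed timestamp (spanning samples
   center−127 … center+128). At 200 Hz / 5 Hz, consecutive windows are
   40 samples apart and overlap by 216 samples. Windows without full
   support inside the recording, and windows straddling a gait-segment
   boundary, are dropped: per-gait evaluation needs unambiguous labels,
   and padding would distort spectral features.
3. **Featurise**: 23 features per channel per window — nine time-domain
   statistics (max, min, mean, median, SD with 1/(N−1), 25th/75th
   percentiles with linear interpolation, kurtosis and skewness with 1/N
   moment estimators; kurtosis raw, not excess) and fourteen
   frequency-domain quantities computed after a symmetric Hann window:
   spectral entropy, spectral energy, and the magnitude and phase angle
   of DFT coefficients k = 1…6 (DC excluded). With 6 channels this gives
   138 features per IMU location; eleven feature sets (`All`, `Limbs`,
   `Sac/Wth`, `Sac/RF`, and the seven singletons) subset locations, so
   `All` has 966 columns.
4. **Select**: sequential floating forward selection (SFFS) with a
   subject-grouped k-fold CV RMSE criterion: a feature is added (or
   floated out) only if it changes the pooled CV RMSE by more than
   0.01 m/s.
5. **Train/evaluate**: five regressor families — SVM (radial), decision
   tree, random forest, least-squares gradient-boosted trees, Gaussian
   process regression — under leave-one-subject-out (LOSO)
   cross-validation. Predictions are pooled across folds before MAE,
   RMSE and nRMSE (= RMSE / mean measured speed, in %) are computed,
   overall and per gait; the full experiment grid is 11 feature sets × 5
   families = 55 models.
6. **Stride baseline**: hoof-on events are detected on the right-front
   limb's z-axis gyroscope, stride frequency is the reciprocal of the
   inter-event interval, and a 2nd- or 3rd-degree polynomial maps stride
   frequency to speed. This is the simple model the feature-based
   pipeline must beat.

## Spectral conventions

Several conventions in the feature definitions are genuinely open; the
package fixes them as follows, and property tests pin each choice.

* DFT: \(X_k = \sum_{n=0}^{N-1} x_n e^{-j 2\pi k n / N}\) (unnormalised).
  Spectral energy is \(\sum_k |X_k|^2\) over all N bins; Parseval's
  identity (\(\sum_k |X_k|^2 = N \sum_n |w_n x_n|^2\)) is asserted at
  1e−6 relative tolerance, which pins the convention.
* Spectral entropy uses the normalised power distribution over the
  one-sided non-redundant bins (k = 0…N/2) with the natural logarithm;
  entropy is bounded by ln(129) for N = 256.
* The "first six coefficients" exclude DC: k = 1…6. The phase angle is
  the two-argument arctangent of \((\sum x_n \sin(2\pi k n/N),
  \sum x_n \cos(2\pi k n/N))\) on the Hann-windowed samples, i.e. the
  negated phase of \(X_k\) — the formula is kept as written in the
  feature definitions rather than silently replaced by `Arg(X_k)`.
* The Hann window is the symmetric variant
  \(w_n = 0.5(1-\cos(2\pi n/(N-1)))\), applied only for frequency-domain
  features; time-domain statistics use the unwindowed (filtered)
  samples.
* Degenerate windows (zero variance, or an all-zero windowed signal) get
  kurtosis/skewness/entropy set to 0 and a degeneracy flag instead of
  NaNs.

## The synthetic-data generator

The generator is the package's study-conditions definition, not a
convenience fixture. Per gait it draws an instantaneous speed process and
synthesises all 42 channels from it:

* **Speed**: a stationary Ornstein–Uhlenbeck process at 5 Hz
  (mean-reversion 0.8 s⁻¹) with per-gait means and SDs of
  1.70 ± 0.17 (walk), 3.30 ± 0.23 (trot), 3.90 ± 0.23 (tölt),
  7.52 ± 1.43 (pace) and 4.95 ± 0.43 m/s (canter), held
  piecewise-constant at 200 Hz. Mean reversion keeps the process smooth,
  bounded and reproducible.
* **Stride frequency**: \(f(v) = a_g + b_g v\) with positive slopes, so
  cadence rises with speed within every gait. The default coefficients
  span roughly 0.85–2.1 Hz across the gait speed ranges — a plausible
  equine cadence range; they are simulator choices, as are all amplitude
  defaults (no published amplitude table exists for this layout).
* **Channels**: a sum of the first three stride harmonics with
  per-location amplitude hierarchies — the z-axis gyroscope dominates on
  limbs (reciprocating limb rotation), the z-axis accelerometer
  dominates on the upper body (vertical displacement) — multiplied by a
  speed-coupling term \(1 + c v\) (default c = 0.15) so that signal
  energy, not only cadence, carries speed information, plus white
  Gaussian sensor noise (0.5 m/s², 8 deg/s).
* **Between-subject variability**: per-subject log-normal amplitude
  multipliers (SD 0.15), uniform phase offsets, and a per-subject
  cadence offset (SD 0.05 Hz). The amplitude SD is channel-weighted:
  limb z-gyroscope (0.3×) and upper-body z-accelerometer (0.6×)
  amplitudes vary least between horses, because swing amplitude and
  vertical displacement are constrained by gait mechanics themselves
  while the remaining axes reflect looser individual habitus. This is
  also what makes features from those channels transfer best across
  subjects and hence rank first under subject-grouped selection, as
  observed on real horses. The cadence offset is what makes the
  stride-frequency-only baseline degrade when subjects are pooled, while
  the ML pipeline — which also sees amplitude information — degrades
  less.
* **The poll**: head-mounted sensors are given a weak speed coupling
  (c = 0.03), small amplitudes, and a non-locomotor head-motion
  component (a smooth mean-reverting disturbance with ~0.3 s correlation
  time, 2.5 m/s² / 12 deg/s) on poll channels only. Voluntary head
  movements overlap the gait band and are unrelated to speed; without
  this component a head sensor would be unrealistically informative,
  because cadence alone is recoverable from any location.

What the generator does **not** emulate: hoof-impact transients,
rider/tack effects, lameness asymmetries, GPS dropouts or clock drift
(IMU and speed streams are perfectly synchronized), or true
biomechanical amplitude scaling between breeds (breed is metadata only).
Passing tests therefore demonstrate that the pipeline machinery is
correct and that its statistical behaviour matches the intended
qualitative structure — not that the specific accuracy numbers would
transfer to real horses.

## Selection and model choices

* SFFS wrapper and folds are not dictated by the method definition:
  the package uses k = 5 subject-grouped folds (grouping prevents
  within-subject leakage during selection) and a small random forest
  (50 trees) as the wrapper — cheap enough to refit thousands of times.
  Fold assignment and every stochastic fit are seeded, so the criterion
  is a deterministic function of the feature subset, ties break toward
  the lower column index, and a hard cap (default 30) guards runaway
  selection.
* Selection runs once per feature set, before LOSO evaluation, on the
  pooled data (nested per-fold re-selection would multiply cost ~40× at
  the full grid; the selection stage precedes the training stage in the
  pipeline design).
* Default hyperparameters are fixed, sensible values per family (random
  forest: 150 trees, √p mtry; boosting: 100 rounds, depth 4, learning
  rate 0.1, histogram splits; SVM: radial, C = 10, ε = 0.1; GPR: RBF
  kernel with automatic length-scale). A tuning mechanism (candidate
  grids scored by subject-grouped inner 3-fold CV on the training folds)
  is implemented in `model_spec(tune = ...)` but the shipped defaults
  carry a single candidate: on the synthetic conditions, tuning moves
  RMSE by far less than the between-seed spread, and the LOSO grid over
  966-column matrices is the budget-dominating step.
* "Boosted trees" is interpreted as least-squares gradient boosting.

## Stride baseline choices

The hoof-on detector is deliberately transparent rather than a
reimplementation of any published event-detection method: band-pass
0.5–8 Hz, positive local maxima above 0.6 × the rolling 2 s maximum
(signed, because harmonic mixtures have asymmetric lobes), an absolute
floor of 20 deg/s (limb swing exceeds this at every gait; sensor noise
does not), and a 0.25 s refractory period. On synthetic signals, whose
events are known by construction, this recovers the fundamental rate to
within a few percent. Stride frequency is paired with the speed sample
nearest the stride midpoint; strides spanning a gait boundary are
dropped.

Polynomial fits are evaluated in-sample (fit and metrics on the same
pooled points). A cross-validated variant would be harsher on the
baseline; in-sample evaluation is the more conservative comparison when
claiming the ML pipeline wins. Note the oddity that a 3rd-degree
polynomial can report a *worse* in-sample RMSE than a 2nd-degree one
only under evaluation schemes other than plain least squares on the same
points; with this package's in-sample definition, RMSE is monotone
non-increasing in degree.

## Problem sizes and numerical notes

The package's own evaluation runs use: a 10-subject cohort with 21 s per
gait segment (~5,000 windows) for the headline LOSO accuracy; five
replicate 6-subject cohorts (~1,400 windows each) for
majority-across-seeds ordering checks (model-family ranking, poll-worst,
baseline-versus-ML, cadence–speed monotonicity); 3-subject cohorts for
structural checks of the 55-model grid; and 150-row, 6-feature planted
problems for the SFFS-versus-exhaustive-search comparison. These sizes
are the package's choices for a desk-scale study; all of them are
configurable.

Windows are featurised vectorised per channel (`mvfft` over the window
matrix), so the full 966-column matrix of a 10-subject cohort builds in
seconds. All model fits are single-threaded and seeded; `ranger`,
`rpart`, `e1071`, `kernlab` and `xgboost` supply the fitters, while
metrics, windowing, features, SFFS and the evaluation harness are
implemented in the package.

## Known limitations

* Synthetic signals are stationary within segments; gait transitions are
  instantaneous. Real transitions produce mixed-content windows that the
  boundary-dropping rule only partially represents.
* The amplitude model is sinusoidal-harmonic; impact-rich waveforms
  (sharp hoof strikes) have broadband content the features would see on
  real data but not here.
* Speed is held piecewise-constant between 5 Hz samples when driving the
  signal model; sub-0.2 s speed fluctuation is not modelled.
* Breed is carried as metadata and affects nothing in the default
  generator; breed-specific signal differences would require their own
  amplitude tables.
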