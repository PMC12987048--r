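---
title: "Methods: three-channel resting-state EEG depression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-channel resting-state EEG depression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The screening problem

`eegscreen` implements an end-to-end pipeline for discriminating major
depressive disorder (MDD) from healthy controls (HC) using only three
prefrontal EEG channels (Fp1, Fz, Fp2) recorded eyes-closed at rest at
250 Hz. The setting is deliberately minimal: a three-electrode frontal
montage is quick to apply, works with portable amplifiers, and frontal
resting-state spectra carry depression-related structure (most prominently a
*frontal slowing* pattern: elevated relative theta power together with
reduced fast activity). The price of a minimal montage is that blind source
separation (ICA/ASR) is underdetermined with three channels, so the pipeline
avoids artifact decomposition entirely and relies instead on per-recording
standardization, window-level quality control, and subject-level aggregation
of many windowed decisions.

The unit of clinical interest is the *subject*, not the analysis window.
Overlapping windows from one recording are strongly correlated, so all
headline evaluation here is subject-level: each window casts a vote, the
subject's label is the modal vote, and the vote confidence is the mean
predicted probability of the winning class across the subject's windows.
Window-level metrics are still reported, but every such report is flagged
descriptive.

## Preprocessing

Recordings are harmonized to the fixed channel order (Fp1, Fz, Fp2) on
ingest, from EDF (`read_edf()`, alias-aware channel resolution) or
three-column CSV (`read_csv3()`). Native amplitude units are never rescaled:
the first processing step, `zscore_recording()`, standardizes each channel
over the full recording (mean removal, division by the within-recording SD,
floored at 1e-8), which removes device gain and unit differences. No
filtering, notching or resampling is applied.

`segment_windows()` cuts each recording into fixed windows of `L` samples
with stride `S = round(L * (1 - p/100))`; at the canonical operating point
`L = 3840` (15.36 s at 250 Hz) and `p = 50`%, the stride is 1920 samples.
Sample indices are 0-based and windows are half-open `[start, start + L)`.
Recordings shorter than one window contribute nothing and are reported as
excluded rather than raising an error.

`qc_filter()` removes windows with non-finite values, with (near-)zero
variance on any channel (tolerance 1e-12), or with saturation. The
saturation rule is necessarily interpretive — "obvious clipping" is not a
formula — and is operationalized as a run of at least 25 consecutive samples
(0.1 s at 250 Hz) pinned within 1e-12 of the channel's recording-level
minimum or maximum; rail-pinned plateaus are the canonical signature of an
amplifier at its limit. The run length is configurable. Subjects losing more
than 20% of their windows to QC are flagged at the recording level; this
threshold is likewise an interpretive default.

## Feature protocol

Each QC-passed window yields three synchronized representations:

1. **Raw window** — the L x 3 z-scored samples.
2. **Per-channel map (3 x 8)** — seven relative band powers plus the
   differential entropy, per channel.
3. **Global vector (17)** — mean, SD, skewness and kurtosis per channel
   (12 values) plus five spectral-balance ratios of channel-averaged
   relative powers: delta/gamma_low, delta/gamma_mid, theta/beta,
   theta/gamma_mid, alpha/gamma_low.

Spectra come from `welch_psd()`: Welch's averaged periodogram with a
periodic Hann taper of length `2 * fs`, 50% segment overlap, per-segment
constant detrending, one-sided density scaling. The grid step is 0.5 Hz for
any sampling rate. Band powers integrate the PSD by the rectangle rule over
the canonical bands delta (0.5–4), theta (4–8), alpha (8–13), beta (13–30),
gamma low/mid/high (30–45/45–70/70–100 Hz). Band membership on the discrete
grid is half-open `[lo, hi)` with the last band closed at 100 Hz, so the
seven bands tile 0.5–100 Hz exactly and the seven relative powers sum to 1
as an identity, not merely within tolerance.

Differential entropy uses the Gaussian closed form `h = ½ ln(2πeσ²)` in
nats, with the sample variance floored at 1e-12; on a z-scored window it
measures residual dispersion and is a monotone transform of log variance.
Moment conventions are fixed and documented rather than discovered:
skewness is the (bias-uncorrected) Fisher–Pearson ratio `m3 / m2^{3/2}`,
kurtosis is Pearson (non-excess) `m4 / m2²`. Ratio denominators are floored
at 1e-12; with QC in place this floor is never reached in practice.

## Augmentation

Training windows — and only training windows; the inference path has no
code path into the augmenters — are perturbed by three label-preserving
operations, applied independently in the order noise → drift → scale
(`augment_window()`):

* additive Gaussian noise, sd 0.01 z-units, probability 0.7;
* a linear drift ramp per channel, endpoint uniform within ±3% of the
  channel's within-window peak-to-peak amplitude, probability 0.3 (the
  amplitude reference is ambiguous in principle; peak-to-peak within the
  window is well defined in z-units and is the choice here);
* per-channel amplitude scaling with factors from N(1, 0.1²),
  probability 0.5.

MixUp (`mixup_batch()`) optionally forms convex combinations of batch items
with weights from Beta(0.2, 0.2). The same mixing weight is applied to the
raw window, the 3 x 8 map, the 17-dim vector and the one-hot labels.
Mixing precomputed features with the raw signal's λ is an approximation —
the features are nonlinear in the signal — but it keeps the three views of
a mixed example consistent and avoids recomputing spectra inside the batch
loop; treating MixUp as an input-space regularizer rather than a generative
model, this is the pragmatic reading.

The squeeze-and-excitation baseline uses its own recipe
(`se_augment_window()`): noise sd 0.02, joint circular temporal shifts up to
10% of the window length, and scaling with sd 0.05, each gated at 0.5.

## Architectures

Three networks are built by the package's own engine (R with C++ kernels
for the memory-bound convolution steps; matrix products go through BLAS):

* **Hybrid fusion model** (`build_hybrid()`): a raw branch of three Conv1D
  blocks (kernels 11/7/5, same padding, ReLU, L2 on every kernel), each
  followed by max-pool 4, batch normalization and dropout — 3840 samples
  shrink to exactly 60 time steps — then a dense embedding (192 units in
  the selected configuration) with 0.5 dropout; a map branch that reads the
  3 x 8 map as a length-8 sequence with 3 channels (Conv1D(3) → pool 2 →
  Conv1D(3) → batch norm → dropout → global average pooling → 128-unit
  dense); a global branch (dense 64 → 32); and a fusion head
  (concatenation, 352 wide → batch norm → dense → dropout 0.5 → 2-unit
  softmax). The searched hyperparameters and their selected values are the
  defaults of `hybrid_config()`.
* **Conv1D-raw** (`build_conv1d_raw()`): 64/128/256 filters, dropouts
  0.25/0.35/0.45, 256-unit head, L2 5e-5, Adam at 8e-4; reference window
  2560 samples.
* **Conv1D-SE** (`build_conv1d_se()`): the same backbone with a
  squeeze-and-excitation module (reduction ratio 8, sigmoid gate) after
  each convolution; Adam at 1e-3; reference window 6000 samples, where the
  pool chain floors 6000 → 1500 → 375 → 93.

Design points fixed here because they are open in principle: the map branch
order is conv → pool → conv → batch norm → dropout ("interleaved" admits
several readings); the fusion-head dropout is 0.5, matching the raw
branch's post-embedding dropout; the hybrid optimizer is Adam (named
explicitly only for the baselines; consistency argues for one optimizer);
MixUp training uses soft-label cross-entropy, which reduces to ordinary
cross-entropy when MixUp is off. Batch normalization uses eps 1e-3 and
running-statistics momentum 0.9: with the short schedules used throughout
(tens of optimizer steps), momentum 0.9 brings the inference statistics to
convergence within ~50 steps, whereas slower updates leave inference
mis-normalized relative to training.

The engine's correctness is established by analytic-vs-numeric gradient
agreement on every layer type (relative error below 1e-3 at machine-level
step sizes) rather than by comparison to a reference framework, since none
is assumed to exist at run time.

## Training protocol

`subject_split()` partitions *subjects*: ~80% development / ~20% held-out
test, with an ~85/15 train/validation split inside development, rounded to
whole subjects. Every window inherits its subject's partition, so leakage
through overlapping windows is impossible by construction;
`assert_no_leakage()` re-verifies this by brute force on the window table.

Class imbalance is handled by inverse-frequency window weights
`w_c = N / (2 N_c)`; under MixUp, a sample's weight is the λ-blend of the
two class weights. Training minimizes class-weighted soft-label
cross-entropy with Adam plus the configured L2 penalty. Validation accuracy
drives two callbacks: learning-rate halving after 5 stale epochs (floor
1e-5) and early stopping after 15 stale epochs with best-validation weights
restored. The patiences are defaults (they are not prescribed anywhere) and
are configurable.

Hyperparameter selection is a two-stage procedure. Stage 1
(`random_search()`) samples 12 configurations uniformly *without
replacement* from the grid spanned by exactly the observed candidate sets
(`search_space()`), trains each briefly, and ranks by best validation
accuracy. Stage 2 (`refine_top_k()`) retrains the top 3 longer and selects
by *refinement-stage* validation accuracy — a short-run peak can collapse
under extended optimization, so the refinement number, not the stage-1
number, decides. The winner is then retrained once on the combined
training and validation subjects before the single test evaluation. Because
that final fit has no validation subjects left to monitor, it runs for the
epoch at which the winning refinement run achieved its best validation
accuracy — the standard budget-transfer rule when early stopping is no
longer available.

Epoch budgets default to 40 (stage 1) and 150 (stage 2); both are
configurable and the test suite uses much smaller budgets (see below).

## Evaluation

`confusion_metrics()` reports accuracy, per-class precision/recall/F1 with
support, macro and support-weighted averages, balanced accuracy, the
Matthews correlation coefficient, and a 95% Wilson score interval on
accuracy. MDD is the positive class throughout, so sensitivity is MDD
recall and specificity is HC recall. MCC returns 0 when a marginal is zero.
Exact voting ties resolve deterministically to the first class index (HC).
Group comparisons on spectral features use Cliff's delta computed exactly
over all pairs and percentile bootstrap CIs of the mean (4000 resamples by
default), always on subject-level aggregates — windows are averaged within
subject first to avoid pseudo-replication.

## The synthetic cohort generator

Because no recorded data ships with the package, `simulate_cohort()`
generates eyes-closed frontal cohorts that make every stage testable. Each
channel is spectrally shaped noise: white Gaussian noise is transformed to
the frequency domain, multiplied by a target amplitude spectrum, and
transformed back. The target spectrum is a 1/f background partitioned into
the seven canonical bands, each scaled by a per-subject band weight, plus a
Gaussian alpha peak (10 ± 1 Hz) carrying 60% of the alpha band's power.
Band weights are log-normal: class mean + subject random effect (SD 0.30 on
the log scale) + small per-channel jitter (SD 0.05). The default patient
contrast encodes the frontal-slowing direction: relative theta up (+0.45
log units, i.e. 1.5 between-subject SDs), high gamma down (−0.45), low
gamma up (+0.30), delta down (−0.30). Working on the log scale keeps powers
positive and mimics multiplicative physiological variability; FFT-domain
shaping gives exact expected band fractions, which is what makes the
parameter-recovery tests sharp.

What the generator does **not** emulate: eye blinks and muscle bursts
(QC fixtures construct plateaus and NaNs explicitly instead), non-stationary
alpha reactivity, inter-channel coherence structure beyond shared band
weights, and any nonlinear dynamics. A pipeline that passes on this cohort
has demonstrated correct mechanics and sensitivity to between-class spectral
structure under realistic between-subject variability — not clinical
validity on recorded EEG.

## Numerical choices and problem sizes

Floors and tolerances: z-score SD floor 1e-8; QC variance tolerance 1e-12;
clipping tolerance 1e-12; DE variance floor 1e-12; ratio denominator floor
1e-12; batch-norm eps 1e-3; Adam eps 1e-7; softmax probabilities clamped at
1e-12 inside the loss, and non-finite probabilities from diverged runs are
mapped to 0.5 so that a pathological configuration ranks last in a search
instead of poisoning it with NaN.

All randomness flows through R's RNG (the C++ dropout kernel uses R's
`unif_rand`), so a single `set.seed()` — seed 42 throughout the canonical
protocol — reproduces splits, initialization, shuffling, augmentation and
bootstraps exactly on a single-threaded run.

The test suite runs everything at reduced problem sizes chosen as the
package's own smoke scale: gradient checks on 64–128-sample windows with
4–8-filter models; the CLI workflow on an 8-subject, 12-second cohort with
512-sample windows; and the end-to-end acceptance run on a 42-subject,
90-second cohort (21 HC / 21 MDD, 30 development / 12 held-out test
subjects) with canonical 3840-sample windows at 0% overlap, a 2-trial
stage-1 search (4 epochs), single-candidate refinement (12 epochs) and a
best-epoch final fit. At that scale the full pipeline trains and evaluates
in a few minutes on one CPU and reaches at least 90% subject-level
majority-vote accuracy on the held-out synthetic subjects.

## Limitations

The package trains on synthetic cohorts by construction; numbers obtained
on them characterize the pipeline, not clinical performance. Window-level
metrics are correlated by overlap and are deliberately second-class.
The saturation rule and the 20% recording-exclusion threshold are
interpretive operationalizations. Probability calibration (e.g. temperature
scaling), ROC analysis and decision thresholds tuned for sensitivity or
specificity are out of scope, as are alternative entropy estimators,
time–frequency image inputs, and attention-based fusion.
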