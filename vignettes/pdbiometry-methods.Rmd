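---
title: "Voice and facial-expression biometrics for early Parkinson's disease screening: methods"
author: "pdbiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voice and facial-expression biometrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbiometry)
```

## The problem

Hypomimia (reduced facial expressiveness) and prosodic voice changes are
soft signs of Parkinson's disease (PD) that can precede the classical motor
syndrome. Both can be measured passively while a person reads a short text
in front of a consumer camera and microphone: the voice carries pauses,
loudness drift and pitch modulation; the face carries blink behaviour and
small mouth/peri-oral movements. `pdbiometry` implements a complete
pipeline for this setting:

1. **Voice features** from a mono PCM WAV of the reading task.
2. **Facial features** from per-frame 2-D landmark tracks (e.g. exported
   from a face-mesh detector; this package does not do face detection).
3. **A feature table** (subjects × features, plus age, sex and diagnosis).
4. **Classification**: sequential forward feature selection wrapped around
   nine classical classifiers, evaluated by stratified 10-fold
   cross-validation (AUROC with bootstrap CI, accuracy, precision, recall,
   F1) and by external validation on an independent cohort.
5. **A synthetic cohort generator** with exact ground truth, so that every
   stage is testable without clinical recordings.

## Voice features

All amplitude arithmetic happens on the 16-bit signed-integer scale
(−32768..32767). `read_wav()` rescales any PCM source depth (8/16/24/32
bits) onto this scale and averages stereo to mono; this matters because the
pause rule below uses absolute thresholds that are only meaningful on a
fixed scale.

* **Frame volume.** The signal is blocked into 25 ms frames; the volume of
  a frame is its mean absolute amplitude (`frame_volume()`, configurable to
  RMS). The exact loudness statistic is a convention; mean absolute
  amplitude keeps the standard thresholds plausible for conversational
  speech at typical recording gain.
* **Pause percentage.** A frame is a pause when its volume falls below an
  adaptive threshold: 30 if the subject's mean frame volume exceeds 100
  (strictly), else 20. Pause percentage is 100 × paused frames / all
  frames.
* **Reading time.** Seconds from the first to the last non-pause frame,
  inclusive. Leading/trailing silence is ignored. It is computed from the
  signal, not from an operator stopwatch.
* **Volume variance.** 100 × (mean volume of first half − mean volume of
  second half) / overall mean volume; with an odd frame count the middle
  frame joins the first half. Negative values mean the voice got louder
  over time. The ×100 scaling puts typical values in the ±dozens range.
* **Average pitch / pitch variance.** Zero-crossing pitch: the signal is
  blocked into 10 ms frames and sign changes between consecutive samples
  are counted per frame (`zero_crossings()`). A zero sample adopts the sign
  of the previous nonzero sample, so touching zero once counts as one
  crossing; a crossing between two samples is credited to the frame of the
  later sample so no crossings are lost at frame boundaries. Average pitch
  is the mean crossing count over *voiced* frames divided by 2 × 10 ms,
  giving Hz (a periodic signal at f Hz crosses zero 2f times per second).
  Pitch variance is the mean absolute crossing-count difference between
  consecutive voiced frames, on the same Hz scale — a prosodic-modulation
  measure that collapses for monotone speech.

Three conventions here were genuinely open and are configurable:

* **Voiced frames only.** Silence produces spurious crossings that would
  dominate a crossing-count average, so pitch features use only non-pause
  frames; the 25 ms pause decisions are resampled to the 10 ms grid by time
  overlap (a pitch frame is voiced if more than half its duration overlaps
  non-pause frames). `pitch_all_frames = TRUE` restores the all-frames
  reading.
* **Hz conversion.** The raw statistic is counts per frame; we divide by
  2 × frame duration because reported population values (~150–170) match
  human fundamental frequency in Hz, not counts. `hz = FALSE` gives counts.
* **Quantization.** Crossing counts are integers, so a pitch of, say,
  157 Hz alternates between 3 and 4 crossings per 10 ms frame. This
  quantization puts a floor under pitch variance that real jitter adds to.
  It is a property of the method itself, not an artifact of this
  implementation.

## Facial features

Landmarks are 2-D points per video frame, named by a `landmark_schema()`:
eye corners and lids per side, mouth corners, upper/lower lip, nose center,
six peri-oral points per side, and a face-width anchor pair. Coordinates
may be in any units: every distance-based feature divides by the
*per-frame* face width (anchor distance), so translation, uniform scaling
and slow zoom drift cancel. The video frame rate is an input, never a
default, because it is recording-specific.

* **Blink fractions.** The eye aspect ratio (EAR) is eye height / eye
  width, averaged over both eyes, then smoothed by a trailing 30-frame
  rolling mean (~1 s at 30 fps; edge frames average what is available). A
  frame is "in blink" at threshold T ∈ {30, 50, 70, 90}% when the smoothed
  EAR is below T% of the mean smoothed EAR; the feature is the in-blink
  frame fraction. Lower T demands deeper closure, so fractions are nested:
  blink(30) ≤ blink(50) ≤ blink(70) ≤ blink(90). "In blink" is any frame
  below threshold — no explicit local-minimum test — because the smoothing
  already suppresses single-frame noise and the quantity of interest is
  total time spent blinking. Whether the threshold should reference the raw
  or the smoothed mean is not determined by the definition; we use the
  smoothed mean.
* **Motion variances.** For a distance series d(t) (outer eye corner to
  mouth corner per side; upper to lower lip; mouth corner to mouth corner;
  nose center to each of six peri-oral points per side), the feature is
  Σ&nbsp;|d(t) − d(t−1)| / face_width(t), divided by the total frame count.
  The divisor is the total frame count (not the number of differences),
  matching the feature's definition as a per-frame movement budget.
* **Mouth angle variance.** Per frame, the acute crossing angle (degrees,
  0–90) between the mouth-corner line and the upper-to-lower-lip line; the
  feature is the mean absolute frame-to-frame angle change. No face-width
  division (angles are scale-free); rigid rotation of the face leaves it
  unchanged. Its absolute unit convention is ours; population magnitudes
  from other implementations are not claimed comparable.

## Feature table and classifiers

`build_table()` joins the 11 facial features, 5 voice features and
demographics into one row per subject, with sex encoded male = 1,
female = 0, and diagnosis as a `control`/`PD` factor (PD positive). Four
feature sets mirror the natural experiments: `face_only`, `voice_only`,
`combined`, `combined_plus_demographics` (18 model columns). An externally
computed phonetic score can ride along as a passthrough column; it is never
computed here.

The nine-classifier registry (`classifier_names()`): entropy-split decision
tree (C4.5-style; exact C4.5 pruning is not reproduced), k-nearest
neighbours (k = 5), radial SVM, Gaussian naive Bayes, random forest (300
trees), logistic regression, depth-wise gradient boosting (xgboost), and
two boosting variants implemented for completeness of the registry:
discrete AdaBoost (SAMME on depth-1 stumps, written in-package because no
installed R library provides it) and a leaf-wise histogram
gradient-boosting configuration (`lightgbm`; LightGBM's growth strategy —
`hist` + `lossguide`, 31 leaves — on the xgboost engine). Hyperparameters
default to common library defaults; none are tuned. Continuous features
are standardized with training-fold statistics for the scale-sensitive
models (kNN, SVM, logistic); tree ensembles consume raw values.

### Selection and evaluation

`sequential_forward_selection()` is a greedy wrapper: starting from the
empty set, repeatedly add the feature that maximizes the pooled
out-of-fold AUROC of the base classifier under stratified k-fold CV
(fold assignment fixed once per call); stop when no candidate improves the
criterion by more than `tol = 1e-4`. Ties break by canonical column order.
AUROC is the selection objective because it is the headline metric of the
evaluation. At least one feature is always returned so downstream models
have an input; on pure noise the path stops there.

`cross_validated_evaluation()` pools out-of-fold predicted probabilities
and reports: AUROC (rank form — the probability a random PD subject
outscores a random control, ties ½, identical to the trapezoidal ROC
area), a stratified-bootstrap 95% CI (2000 replicates by default),
and accuracy/precision/recall/F1 at the fixed 0.5 probability cutoff.
`run_experiment()` adds the two-cohort design: selection + CV on the
training cohort, refit on the full training table with the selected
features, then scoring of a disjoint validation cohort (shared subject ids
are a hard error). Refitting on the full training table (rather than
freezing a fold ensemble) is our reading of the validation protocol.
`selection_coverage()` ranks features by the percentage of classifiers
that selected them.

Everything downstream of the master seed — subject draws, fold
assignments, classifier randomness, bootstrap — derives from it through a
deterministic fan-out, so the full chain is bit-reproducible.

## The synthetic cohort generator

No clinical recordings ship with (or are downloadable by) this package, so
`simulate_cohort()` / `simulate_feature_table()` generate PD-like and
control-like subjects with exact ground truth. The defaults are the study
conditions: group means/SDs chosen to reproduce the direction and
approximate magnitude of published clinical group differences — controls
pause ~13% of frames vs ~21% for PD, higher pitch jitter (mean |ΔF0| ~15 Hz
vs ~7 Hz), more and deeper blinks (8/min at 95% closure vs 5/min at 80%),
slightly longer PD reading time and stronger PD volume drift — while
average pitch and all mouth-motion parameters are drawn identically in
both groups, so feature selection faces true negatives. `effect_scale`
multiplies *every* group difference (means, dispersions, and the age
shift), so `effect_scale = 0` yields exactly exchangeable groups for null
experiments.

**Voice.** Voiced/pause structure is laid out on the extraction-aligned
25 ms frame grid (first and last frames always voiced; pause runs ~0.2 s
geometric), so the planted pause fraction is recovered almost exactly.
Voiced frames carry a phase-continuous sinusoid whose instantaneous
frequency is redrawn every 10 ms around F0 with the planted jitter SD,
under a linear amplitude drift; pause frames are a small positive
near-silence floor that produces no spurious zero crossings. Sinusoids
rather than synthesized speech: the features (crossings, amplitude,
pauses) are insensitive to phonetic content, and sinusoids give analytic
ground truth. A fixed phase offset keeps zero crossings away from exact
sample positions, where floating-point sign noise would jitter counts.

**Face.** A canonical neutral layout is animated with raised-cosine blink
valleys (Poisson count, configurable depth and duration), sinusoidal mouth
opening/width/corner-tilt motion with matched peri-oral radial motion,
small landmark jitter, and a slow global translation + zoom drift that the
normalization must cancel. The default blink lasts 60 frames (2 s) —
longer than a physiological blink — deliberately: the mandated 30-frame
rolling mean attenuates valleys shorter than the window below the deeper
relative thresholds, so blinks must outlast the window for the 30–90%
thresholds to dissociate. Planted blink time is stated on the same
smoothed scale the detector uses (trailing-mean of the noiseless closure
curve > 50% of baseline), which isolates what the recovery test should
check: geometry, noise, drift and thresholding, not the smoothing
identity.

**What the generator does not emulate.** Phonetic content, formants,
consonant noise, room acoustics; 3-D head pose and perspective;
physiological blink dynamics; jaw/voice tremor subgroups; correlations
between voice and face severity within subject. Passing tests therefore
demonstrate that the extraction and evaluation machinery is correct and
well-calibrated on signals with known structure — not that the pipeline's
discrimination numbers transfer to clinical recordings. Relative modality
strength in particular (facial vs voice features) is not calibrated to any
clinical cohort.

## Problem sizes and numerical choices

* Cohort-scale runs (tests and the acceptance script) use 100 subjects per
  group per cohort, ~8–15 s of speech per subject at 16 kHz, and 30 s of
  video at 30 fps. The features are sample-rate invariant (demonstrated by
  tests), and the planted effects do not depend on recording length, so
  this keeps a full two-cohort experiment within minutes on one CPU. The
  single-subject default remains 44.1 kHz.
* Degenerate inputs are hard errors with classed conditions: zero eye/face
  width or a zero-length mouth line (`degenerate_geometry`), all-pause
  signals for reading time, zero mean volume for volume variance, fewer
  than two voiced frames for pitch variance (`undefined_feature`).
* SFS stopping tolerance 1e-4 on AUROC; bootstrap CI percentile-based;
  classifier probability ties at the 0.5 cutoff resolve to the positive
  class (`>=`).
* AdaBoost stops early if a stump is no better than chance or perfect; a
  fully degenerate fit falls back to the class prior as a constant score.

## Known limitations

* The zero-crossing pitch tracker is first-harmonic only and assumes a
  reasonably clean signal; no denoising or high-pass is applied by default.
* The loudness statistic and pause thresholds assume recording gain that
  puts conversational speech well above 30 on the 16-bit mean-absolute
  scale; heavily attenuated recordings will classify as all-pause.
* EAR blink detection with a 30-frame rolling mean cannot see blinks much
  shorter than the window at the deeper thresholds (see above).
* The C4.5 and LightGBM registry entries are the documented approximations
  above, not the original algorithms.
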