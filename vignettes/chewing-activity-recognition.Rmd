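---
title: "Recognizing food intake and physical activity from eyeglasses-mounted sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing food intake and physical activity from eyeglasses-mounted sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chewsense)
```

## The problem and the measurement model

Automatic dietary monitoring fails most often when the wearer moves: gait
and speech artifacts leak into whatever sensor is watching the jaw. The
system this package models attacks that problem with two complementary
channels mounted on ordinary eyeglasses:

* a **piezoelectric strain sensor** taped over the temporalis muscle, which
  produces a voltage proportional to the jaw strain of each chew, sampled at
  1000 Hz;
* a **three-axis accelerometer** in the temple-mounted electronics, sampled
  at 100 Hz, which sees gait and posture.

Chewing is a strongly rhythmic activity with a fundamental frequency between
0.94 and 2.17 Hz, so the strain channel is low-pass filtered at 3 Hz and
both channels are analyzed in non-overlapping 3-s epochs -- long enough to
contain several chews even at the slowest chewing rate. Each epoch is
described by four time-domain features per channel (range, sample standard
deviation, energy, waveform length) and assigned one of four classes:
eating while sitting (1), sedentary (2, which merges quiet sitting and
talking), eating while walking (3), and walking (4).

Two linear-SVM architectures map features to classes:

* **single multiclass**: one one-vs-all linear SVM on the fused 8-feature
  vector;
* **two-stage**: a food-intake detector on the four piezo features and a
  walking detector on the four accelerometer features, whose signed outputs
  are fused by four fixed decision rules (intake/no-walking is eating while
  sitting, and so on).

Evaluation is leave-one-subject-out (LOSO): train on all epochs of all but
one subject, validate on the held-out subject, rotate. This is the honest
protocol for a wearable -- it measures generalization to a person the
classifier has never seen.

## What the simulator emulates

The original recordings are not public, so the package ships a seeded
simulator that reproduces the *statistical structure* the classifiers rely
on, at the study's scale (ten subjects, five activities per subject).

Per activity segment:

* **Chewing** (`synth_chew_signal()`): an amplitude-modulated oscillation at
  the subject's chewing rate plus a second harmonic at 0.4 of the
  fundamental's amplitude, organized in chewing bouts of 10--30 s separated
  by 2--5 s pauses (bite preparation, swallowing), on white sensor noise.
  The pushbutton annotation channel is 1 exactly during bouts.
* **Walking** (`synth_accel()`): each axis carries the projection of
  gravity for a per-subject device tilt (up to 8 degrees), white noise, and a
  gait oscillation at the step rate with a second harmonic -- strongest
  vertically, attenuated fore-aft, with mediolateral sway at the stride
  (half-step) rate. Sedentary stretches instead get sparse posture-shift
  transients whose amplitude scales with the noise floor.
* **Talking**: utterance-gated bursts of a weak 2.5--4 Hz jaw oscillation at
  0.12 of the chewing amplitude on the piezo channel.
* **Crosstalk**: while walking, a fraction (`crosstalk_gain`, default 0.15)
  of the gait oscillation leaks into the piezo channel, so distinguishing
  eating-while-walking from walking is not trivially easy.

### Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `chew_rate` | drawn U(0.94, 2.17) | Hz | the physiological chewing-frequency range |
| `step_rate` | drawn U(1.8, 2.2) | Hz | step cadence near 2 Hz at a 3 mph walk |
| `chew_amplitude` | drawn U(0.8, 1.2) | sensor units | order-unity strain signal; per-subject electrode coupling varies |
| `gait_amplitude` | drawn U(0.25, 0.35) | g | typical vertical acceleration swing at 3 mph |
| `noise_sd` | drawn U(0.03, 0.07) | sensor units | ~5% of chew amplitude; a clean skin-mounted film sensor |
| `accel_noise_sd` | drawn U(0.015, 0.025) | g | consumer MEMS accelerometer noise at 100 Hz |
| `crosstalk_gain` | drawn U(0.10, 0.20) | -- | moderate mechanical coupling of gait into the strain film |
| segment durations | 165, 96, 180, 81, 132 s | s | chosen once so that ten subjects cut into 3-s epochs give a class balance close to the study's 322/1155/271/437 |

The protocol durations deserve a note: the original study does not state how
long each activity lasted, only the total epoch counts per class. The
defaults above are fitted to reproduce that class balance (ten subjects
yield 320/1150/270/440 epochs of 3 s, 2180 total) and are multiples of 3 s,
so no epoch straddles an activity boundary under the default protocol.
Boundary-straddling epochs are still handled (majority-overlap labeling,
ties to the earlier segment) for custom schedules.

The profile separates the piezo noise level (`noise_sd`, sensor units) from
the accelerometer noise level (`accel_noise_sd`, g): the two channels are
different physical quantities and a single dimensionless level would couple
them for no physical reason.

Seeding is hierarchical: the master seed draws the per-subject parameter
profiles, and each subject's recording is generated from its own derived
seed (`master_seed + 10007 * i`, kept inside the 32-bit integer range), so
cohorts are reproducible bit-for-bit and subjects are independent.

### What the simulator does *not* emulate

Food-texture-specific chewing dynamics, swallowing and liquid intake,
head-motion artifacts other than speech, Bluetooth packet loss, ADC
quantization, electrode detachment, and any physiological detail of the
temporalis EMG. Passing the end-to-end tests therefore shows that the
pipeline's machinery is correct and that the architecture separates classes
*whose features are distributed like the simulator's output* -- it does not
re-establish the published accuracy on real chewing data, which is exactly
why the published confusion matrices are bundled and recomputed separately.

## Signal conditioning choices

The filter family and order are not stated in the original description, so
the package uses the standard maximally flat choice: a 4th-order Butterworth
low-pass at 3.0 Hz applied forward and backward. Zero-phase filtering keeps
chew peaks aligned with the annotation channel. Forward-backward application
squares the magnitude response, so the band-edge attenuation at 2.17 Hz is
about 0.6 dB -- an acceptable cost for phase linearity, and irrelevant to
features computed per epoch. The implementation pads each end with about two
seconds of odd-reflected signal before filtering; without this, startup
transients on a signal with a DC offset (gravity, strain bias) would corrupt
the first and last epochs. Filtering happens once per recording, before
segmentation, so epoch boundaries see no filter edges at all.

Net acceleration is the Euclidean magnitude of the three axes with gravity
included; the energy feature consequently carries a DC contribution, which is
accepted as-is (mean removal is deliberately *not* applied, keeping the
feature definitions exactly as stated).

One printed feature formula -- the standard deviation -- omits the squaring
and square root in the source table; the package implements the conventional
N−1 sample standard deviation, since the formula as printed would be
near-zero for any approximately symmetric oscillation.

## Classifier choices

* **Standardization**: features are z-scored inside the model using
  *training-fold* statistics only. SVMs are scale-sensitive and the energy
  feature spans orders of magnitude; computing the scaler from the training
  fold prevents leakage from validation subjects.
* **Regularization**: the original work used a GUI tool without reporting
  hyperparameters; the package defaults to C = 1 and exposes it.
* **Tie-breaking**: the one-vs-all arg-max breaks ties toward the lowest
  class code; a stage score of exactly zero counts as +1. Both are arbitrary
  but fixed, which is what determinism requires.
* **Two-stage ROC scores**: the two-stage classifier natively outputs only
  hard labels. For one-vs-rest ROC analysis each class k with rule
  combination (u_k, v_k) gets the continuous score
  min(u_k * s_chew, v_k * s_acc). This is monotone in both stage scores,
  reduces to one stage's score when the other is confident, and recovers the
  hard label at threshold 0.

## Evaluation conventions

Metrics come from the pooled confusion matrix (all validation folds
combined). The published two-stage table is exactly self-consistent under
pooling -- every printed precision, recall and F1 is recovered from its
counts after two-decimal rounding -- which is the evidence that pooling is
the right default. The published single-classifier table's printed
precision/recall do *not* equal its own pooled counts (its eat-sit recall
prints as 96.58% while the counts give 310/322 = 96.27%); they appear to be
averaged over folds. The package therefore also reports per-fold macro
metrics (`fold_macro` in every report) rather than silently "correcting"
either table, and the recomputation of that table's F1 values goes through
the printed precision/recall pairs, which *is* exact.

Percentages are rounded half-up to two decimals only at reporting time;
macro averages are unweighted arithmetic means over the four classes,
computed before rounding. Degenerate 0/0 precision-or-recall cases are
defined as 0. AUC is the trapezoidal area of the threshold-sweep ROC with
tied scores grouped, which makes it exactly the Mann-Whitney statistic
P(score+ > score-) + 0.5 P(equal); the tests verify this identity against
exhaustive pair counting and against an independent ROC implementation.

The cross-validated experiment sizes used throughout -- ten subjects of
654 s each, 2180 epochs, ten LOSO folds, both architectures plus a
label-shuffled negative control -- run in well under a minute and were
chosen as the smallest faithful replica of the study design, not as a
statistical improvement on it.

## A worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(n_subjects = 10, master_seed = 42)
feats <- featurize_cohort(cohort)
report <- run_experiment(feats, arch = "two_stage")
print(report)
```

`print(report)` renders the pooled confusion matrix in the same layout as
the published tables, with per-class recall/F1 on the rows, precision
underneath, and the macro means and mean AUC last.

## Known limitations

* Linear decision functions only; the published system also reports only
  linear SVMs, but nothing in the API anticipates kernels.
* The simulator's class structure is deliberately favorable: features are
  near-separable by construction, so synthetic macro-F1 values land in the
  high 90s and cannot arbitrate between the two architectures the way noisy
  human data did. Epochs falling inside chewing pauses are the main
  synthetic error source (they are labeled "eating" by schedule but contain
  no chews), which is also a real phenomenon of pushbutton-annotated data.
* The annotation channel is generated but, matching the original labeling
  procedure, the ground-truth schedule -- not the pushbutton trace -- defines
  epoch labels.
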