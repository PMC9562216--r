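---
title: "Detecting gait events from foot-marker kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events from foot-marker kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitevents)
```

## The problem

Clinical gait analysis segments walking into gait cycles bounded by two
events per foot: initial contact (IC), when the foot first touches the
ground, and toe-off (TO), when it leaves it. In instrumented laboratories
these events come from force plates — the vertical ground reaction force
(vGRF) crossing a threshold, conventionally 20 N — or from laborious manual
annotation of video when clean force-plate hits are unavailable. Both
routes break down in paediatric and pathological gait: short steps land
several feet on one plate, assisted walking cannot use plates at all, and
manual annotation is slow and operator-dependent.

This package detects IC and TO automatically from the kinematics of four
foot markers of the Conventional Gait Model — calcaneus (HEE), distal
metatarsal head (TOE), hallux (HLX) and proximal fifth metatarsal (PMT5) —
as captured by an optical motion-capture system at 150 or 300 Hz. It is
aimed at movement laboratories that see heterogeneous pathological
patterns, which are grouped here by the foot region making initial
contact: heel-strike (HS), midfoot (MF, flat or lateral contact) and
forefoot (FF, toe-walking).

## The method

The detector is a per-frame sequence labeller:

1. **Features.** Trials are downsampled to 150 Hz; marker velocities are
   forward differences, `v[n] = (s[n+1] - s[n]) / dt` with `dt = 1/150` s.
   Each marker contributes 6 channels (x, y, z position and velocity), so
   the two- and three-marker combinations used throughout
   (`HLX|HEE`, `TOE|HEE`, `HLX|PMT5|HEE`, `TOE|PMT5|HEE`, `HLX|TOE|HEE`)
   yield 12 or 18 input channels.
2. **Targets.** Nominal event times are uncertain — inter-rater spread of
   manual annotation and threshold variability of force events are on the
   order of 16 ms — so each event is encoded as a peak-normalized Gaussian
   bump with a standard deviation of 16 ms rather than a one-hot frame.
   Overlapping bumps combine by pointwise maximum so targets stay in
   [0, 1].
3. **Model.** A stacked bidirectional LSTM followed by a per-frame linear
   map and sigmoid emits an event-probability curve. Looking both backward
   and forward in time is what makes the labelling accurate — and what
   rules out real-time use. One model is trained per event type and marker
   combination; the tuned hyper-parameter presets
   (`hyperparam_preset("IC:TOE|HEE")`, etc.) cover all ten combinations.
4. **Training.** Windows of 150 frames are cut around each annotated
   event with a uniform random offset of up to ±30 frames, so event
   position within the window is not learnable. Batches are drawn from the
   HS/MF/FF groups in a 4:2:1 ratio to counteract the cohort imbalance.
   The loss is binary cross-entropy with the positive class up-weighted by
   `sum(1 - y) / sum(y)`; the optimiser is Adam. Splits are by subject —
   a subject is never in more than one of train/validation/test — and the
   repeated-training protocol retrains over ten different train/validation
   splits against one fixed test set, reporting mean ± SEM.
5. **Detection and scoring.** A standard peak detector extracts events:
   local maxima strictly above 0.5, at least 0.25 s apart, plateaus
   resolved to their midpoint. A truth event counts as *detected* when at
   least one prediction falls within ±16 ms (inclusive); a prediction is a
   *true positive* when at least one truth event is within ±16 ms. These
   are coverage percentages, not a one-to-one assignment, so recall and
   precision are reported independently, with false-alarm rate defined as
   100 − precision. Matched predictions contribute signed timing errors,
   summarised as a percentile curve and 95%/99% trimmed means (mean of the
   best 95%/99% of absolute errors).

The recurrent network itself is implemented in-package as a batched pure-R
bidirectional LSTM (forward pass, backpropagation through time, Adam),
relying on BLAS matrix products; its gradients are verified against
numerical differentiation in the test suite.

## The synthetic-gait simulator

No clinical recordings ship with the package; instead `simulate_trial()`
and `simulate_cohort()` generate barefoot walking passes with exact ground
truth, which drive every test. The simulator is a piecewise kinematic
template, not a musculoskeletal model:

* Strides follow the configured cadence and speed; stance occupies 60% of
  the stride for HS/MF and 65% for FF, literature-typical values for
  paediatric gait.
* During stance the foot is stationary in the progression direction;
  during swing it advances one stride length along a minimum-jerk profile.
  Vertical marker motion follows pattern-specific keyframe curves with
  cosine easing: at IC the heel is lowest for HS (heel-pivot then forefoot
  lowering), the forefoot lowest for FF (heel raised throughout), and all
  four markers level for MF.
* A synthetic vGRF is emitted per stance: a double-bump profile peaking
  near 1.5 body weight with a mid-stance valley, with steep loading and
  unloading ramps over the first and last 8% of stance so the 20 N
  crossing sits within about 2 ms of the true event — the internal
  consistency check that force-threshold extraction recovers the generated
  truth within one frame.
* Observation noise is i.i.d. Gaussian per coordinate, 1 mm by default
  (about a tenth of a 9.5 mm marker diameter); cohorts draw per-subject
  cadence, speed, foot length, body mass and side, and allocate patterns
  HS:MF:FF = 4:2:1 by largest-remainder rounding.

What the simulator does **not** emulate: soft-tissue artefact and marker
occlusion statistics, crouch and other proximal-joint deviations, step
width and turning, double support asymmetries, and inter-stride
variability beyond smooth parameter draws. Passing the end-to-end
benchmark on synthetic data therefore demonstrates that the pipeline —
features, targets, training, inference, peak extraction, scoring — is
internally correct and learnable at desk scale; it does not certify
clinical detection rates, which depend on real marker data.

## Numerical and design choices

* **Velocity alignment.** The forward difference is one frame shorter than
  the position series; the final velocity frame is replicated so both
  share one grid.
* **Coordinate canonicalization.** The horizontal principal axis of the
  heel trajectory is rotated to +x (sign fixed by net displacement), the
  first-frame mid-foot centroid is subtracted, and left feet are mirrored
  across the sagittal plane, so walkway direction and side cannot become
  learnable shortcuts. The operation is idempotent and rejects standing
  trials.
* **Standardization.** Channels are z-scored with training-set statistics
  (positions are mm-scale, velocities mm/s-scale; without this the loss
  surface is badly conditioned). The scaler travels inside the checkpoint.
* **Window edges.** Windows at trial edges are shifted inward rather than
  zero-padded; padding adds no information and biases the boundary frames.
* **Offset distribution.** Window offsets are uniform over the 61 integers
  in [−30, 30].
* **Target truncation.** The Gaussian bump is evaluated within ±4σ and
  zero outside; at 150 Hz the bump spans ±10 frames.
* **Peak rules.** "Above 0.5" is strict; the boundary of the ±16 ms
  tolerance is inclusive. Peaks closer than the 0.25 s separation are
  pruned keeping higher peaks first. A plateau yields its midpoint frame.
* **Trimmed mean.** Defined as the mean of the smallest
  `ceiling(keep_fraction * n)` absolute errors.
* **Force-event debouncing.** Threshold crossings are continuous times by
  linear interpolation; crossings closer than 50 ms are removed in
  adjacent pairs, which provably preserves IC/TO alternation; a leading
  downward crossing (stance already in progress at trace start) is
  dropped.
* **Inference.** Full-sequence inference is the default — a bidirectional
  recurrent network accepts any length, and window stitching adds
  artefacts; a sliding-window mode (150 frames, stride 75, overlaps
  averaged) exists for very long records.
* **Pattern classification.** The default rule compares marker heights at
  IC with a 5 mm contact margin (half a marker diameter): heel clearly
  lowest → HS, forefoot clearly lowest → FF, otherwise MF; trial label by
  majority vote with ties resolved to MF, which mirrors the clinical
  convention of treating MF as the residual category. An alternative mode
  thresholds the foot's sagittal pitch angle (HEE→TOE elevation) at IC
  with user-supplied degree cutoffs; true ankle dorsiflexion would need a
  shank segment, which the four foot markers cannot provide.
* **TOE naming.** The distal forefoot marker is variously documented as
  first- or second-metatarsal; the alias table accepts both designations
  and does not adjudicate.

## Problem sizes used in the shipped checks

The test suite trains the small profile (1 bidirectional layer, 64 hidden
units, learning rate 0.003) on about 600 IC windows from 60 training
subjects of an 80-subject synthetic cohort (HS:MF:FF = 4:2:1, 10 strides
each, 1 mm noise), validates on 10 subjects and evaluates on 10 held-out
subjects; 20 epochs of batch-64 Adam suffice for the validation loss to
plateau. These sizes were chosen so the whole pipeline exercises every
code path in minutes on a laptop core while leaving clear headroom above
the benchmark thresholds (IC recall ≥ 85%, precision ≥ 80% at ±16 ms). The
full Table-style presets (2–5 layers, 256–512 hidden) are the defaults for
real data and train the same way, only longer.

## Known limitations

* The pure-R network trains desk-scale models comfortably but is not a GPU
  framework; expect minutes, not seconds, for the large presets on long
  cohorts.
* Detection is offline by construction (bidirectional context).
* Occluded-marker trials are excluded, not gap-filled.
* The C3D reader covers the common modern subset: little-endian files with
  floating-point point data; integer-scaled or legacy byte orders are
  rejected with a clear message.
* Synthetic benchmarks bound internal correctness only; clinical
  performance must be established on annotated laboratory data.
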