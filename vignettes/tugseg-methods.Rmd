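---
title: "Segmenting the Timed Up-and-Go test: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the Timed Up-and-Go test: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tugseg` turns a skeleton-joint recording of a Timed Up-and-Go (TUG) trial
into a per-frame subtask labeling, the six TUG event times, and the derived
clinical quantities (subtask durations, walk speeds, total TUG time). This
vignette is the package's account of how each stage works, which knobs
matter, what the synthetic data generator does and does not establish, and
where the design was genuinely open.

## The segmentation problem

A TUG trial has a strict temporal grammar: the subject sits, rises, walks
3 m, turns, walks back, sits down, and sits still. We classify every frame
into one of five states — `sit`, `sit_to_stand`, `walk`, `turn`,
`stand_to_sit` — where the outbound and return walks share one class and are
distinguished positionally. The six events separating consecutive subtasks
follow the standard annotation guideline: StartMove and EndSit are the
instants the trunk crosses a 45-degree inclination rising from / sinking
into the chair; StartWalk is the first step off the ground; StartTurn,
EndTurn and StartSit bound the turn and the final approach.

## Preprocessing

Three steps, in order, per trial:

1. **Axis matching** (`align_axes()`). Camera placement is arbitrary, so the
   recording is rotated about the vertical axis until the first principal
   direction of the centered horizontal pelvis track lies along +x, with the
   outbound excursion positive (sign resolved by the first large
   displacement). The transform is rigid; the vertical coordinate is
   untouched. Recordings whose horizontal pelvis span is below 0.5 m are
   rejected — there is no walking axis to find.
2. **Low-pass filtering** (`butterworth_lowpass()`): 4th-order Butterworth,
   0.3 Hz cutoff at 30 Hz sampling. No signal-processing package ships in
   the target environment, so the bilinear-transform design and the
   forward–backward filter (odd-extension padding, steady-state initial
   conditions) are implemented in the package and verified against frozen
   reference coefficients and the analytic magnitude response. We default to
   **zero-phase** (forward–backward) filtering: at a 0.3 Hz cutoff a causal
   pass would delay every event by a visible group delay (~1 s), and the
   pipeline is offline; a `causal` mode is retained for ablation.
3. **Min-max normalization** (`minmax_normalize()`), mapping each channel of
   each trial onto [0, 1]. Normalization is **per trial, per channel**: its
   purpose is to remove between-subject scale (body height, camera
   distance), and the per-trial reading needs no training-set statistics at
   inference time. Whether the original pipeline normalized per trial or
   over the whole dataset is unstated; per-trial is the strictest choice.
   Constant channels are mapped to zeros with a warning.

The filter-then-normalize order matters: normalizing first would let noise
extremes set the scale.

## The dilated TCN classifier

Each frame is classified from a window of `W = 8` consecutive preprocessed
frames centered on it (offsets −4…+3, edges replicated), giving per-frame
labels at stride 1. The model is three temporal blocks of two dilated
convolutions each (kernel 3; dilation 1, 2, 4 across blocks; ReLU; residual
connection per block, 1×1-projected when widths change) followed by a dense
softmax head on the flattened window features. Defaults: learning rate
7e-5, Adam, batch 1024, categorical cross-entropy, early stopping on
validation loss with patience 50, best-epoch weights restored, subject-wise
6:2:2 train/validation/test split. All randomness (splits, initialization,
shuffling) sits behind one seed; identical configurations reproduce
identical histories bit for bit.

Design points that were open:

* **Window-to-frame mapping.** How a window prediction maps onto frames is
  not specified by the architecture family; we predict the center frame of
  each stride-1 window, which yields exactly one distribution per frame and
  makes the receptive-field contract testable (perturbing frames outside a
  frame's window cannot change its prediction).
* **Channel plan.** The published parameter counts for this architecture
  family are mutually inconsistent at the ±2 level under any single
  affine-in-(k², W) law, so the exact layer composition is not recoverable;
  counts are therefore *reported, not enforced* (`count_parameters()`). The
  default plan 16→16→24 (6,877 parameters) was chosen once for single-CPU
  training speed and is a package default, not a reproduction target.
* **The seated padding frames** are modeled as a first-class `sit` class
  rather than masked out; the canonical template treats the leading and
  trailing sit as optional segments.
* Batch normalization and dropout are omitted; they belong to the recurrent
  baseline, not this model.

The production forward/backward passes are compiled (RcppArmadillo, im2col
plus one GEMM per layer); a pure-R reference implementation lives alongside
and the test suite requires both to agree to 1e-12 and the reference to
match finite-difference gradients.

## Order-constrained correction ("DTW postprocessing")

Frame classifiers make fragmentation errors — short runs of a wrong class
inside a correct segment. The TUG grammar forbids them: any valid labeling
is `sit*, sit_to_stand+, walk+, turn+, walk+, stand_to_sit+, sit*`. We
implement the correction as the optimal monotone alignment of the frame
sequence to that 7-slot template: with local cost `1 − p_t(class(slot))`,
dynamic programming finds the boundary placement minimizing total cost
(equivalently maximizing the total probability credited to the assigned
classes). This is the natural reading of "aligning predictions to the
canonical subtask string by dynamic time warping"; no cost function was
published, and soft probabilities are used with hard labels as the one-hot
special case. Ties are broken toward the **earliest feasible boundaries**,
which makes the output deterministic; the test suite checks optimality and
the tie-break against exhaustive enumeration of all boundary placements.
Boundary *shift* errors at true transitions are inherently uncorrectable by
an order constraint and are out of scope.

Events are the first frames of slots 2–7; times are frame index / fps with
0-based frames. Total TUG time is EndSit − StartMove.

## The synthetic cohort

The study's recordings are not public, so the package carries a simulator
(`simulate_tug()`) as a first-class, tested module. It reproduces the
protocol's *stated world*: 30 Hz sampling; a 3 m out-and-back path from a
chair; seven ordered phases with 1 s seated padding at each end; total
durations drawn truncated-normal with the published cohort means (healthy
young 11.34 s, older adults 15.33 s, stroke 43.11 s); a random camera
azimuth so axis matching is always exercised; Gaussian position noise.
Kinematics are minimum-jerk displacement profiles per phase with a
sinusoidal trunk-pitch sweep through the transitions, built so the trunk
pitch crosses 45 degrees *exactly* at the StartMove and EndSit ground-truth
instants — the same criterion the human annotators used. Secondary joints
(spine chest, head, hands, ankles) are pelvis-relative offsets with
phase-gated arm-swing and step oscillations.

Values the study does not state, chosen once and documented here rather
than tuned: duration SDs of 1.2 / 1.8 / 6.0 s per group (coefficients of
variation ~10–14%, typical of repeated TUG measurements); active-phase
fractions 15/30/10/30/15% of the non-padding time for sit-to-stand / walk /
turn / walk back / stand-to-sit; seat height 0.45 m; noise SD 5 mm per
coordinate. Ground-truth labels and events always derive from the phase
plan, never from the noisy signal, so noise level can never corrupt the
labels.

What a green test on synthetic data does and does not establish: it shows
the pipeline is *internally correct* — the classifier can recover a
learnable grammar, the correction is optimal, events are extracted exactly,
metrics compute what they claim. It does not establish the published
real-data accuracies: real stroke gait variability, tracking dropouts, and
annotator disagreement are absent from the simulator, and the study's
headline numbers (95.5/94.5/93.6% by group) are explicitly not reproduction
targets.

## Evaluation

Per-subtask one-vs-rest precision, recall and F1 (harmonic mean); overall
frame accuracy (micro-average); per-event absolute timing errors aggregated
as MAE with *population* STD (the variant used is unstated; population SD
is the deterministic choice); total-TUG-time MAE, which cancels common
shifts; subtask durations and walk speeds (3 m / duration). Per-subtask
timing error is read as a *duration* error (the alternative — boundary
error — is recoverable from the event table). Undefined per-class metrics
(class absent from predictions and truth) are reported as `NA` with a
warning and excluded from macro averages. Inter-rater reliability of event
labels uses ICC(2,1) — two-way random effects, absolute agreement, single
rater — implemented from the mean-squares decomposition because no
psychometrics package ships in the target environment; it is verified
against an explicit ANOVA oracle and a frozen external reference value.

## Numerical and degenerate-input choices

* Filter: signals shorter than 3× the order are rejected; padding length
  `min(3·(order+1)·…, T−1)` shrinks for short signals.
* Correction: inputs shorter than 5 frames cannot host the five mandatory
  segments and are rejected; probability rows are validated.
* Splits: sizes use floor + largest-remainder so 50 subjects give exactly
  30:10:10 and five folds of 10.
* Early stopping uses strict improvement (`<`); equal loss counts as no
  improvement.
* All error conditions carry typed condition classes (`tug_*_error`) so
  callers can test them precisely.

## Known limitations

* The simulator's gait is kinematically plausible but not biomechanically
  validated; pathological gait differs from healthy gait only by duration
  scaling.
* Training runtime on one CPU bounds the default channel plan; wider plans
  (e.g. 32→32→48) train slower but are fully supported via `tcn_config()`.
* No gap-filling for missing skeletons — trials with tracking dropouts were
  excluded at the protocol level and are out of scope here.
* The order constraint cannot fix boundary-shift errors; improving those
  requires boundary-aware losses or post-hoc refinement, both future work.
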