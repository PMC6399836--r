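---
title: "Classifying intended torque direction at the hemiparetic shoulder and elbow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying intended torque direction at the hemiparetic shoulder and elbow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myointent)
```

## The problem

After stroke, many survivors present with abnormal synergies: involuntary
coupling of torques and muscle activity across the joints of the paretic
arm. The flexion synergy links shoulder abduction with elbow flexion,
external rotation and horizontal abduction; the extension synergy links
their opposites. A wearable shoulder exoskeleton that could read the
user's *intended* movement from proximal signals could support abduction
effort and thereby release the distal limb from synergy-driven flexion.
The prerequisite is an intent decoder that stays accurate despite the
coupling.

`myointent` implements the standard offline decoding paradigm for this
question: participants produce maximal isometric torques in eight
single-DOF directions (elbow flexion/extension EF/EE, shoulder
abduction/adduction AB/AD, external/internal rotation ER/IR, horizontal
ab/adduction HAB/HAD) while eight surface EMG channels and a 6-DOF load
cell at the forearm are recorded at 1 kHz in 5 s trials. Overlapped
windows of these signals feed a linear discriminant classifier, and
trial-wise leave-one-out cross-validation estimates how well each of four
signal sources — EMG time-domain features, raw load-cell means, derived
joint-torque means, and EMG + load cell combined — separates the eight
intents.

Because raw recordings of this kind are not publicly deposited, the
package pairs the analysis with a synthetic-trial generator whose
statistical structure matches what the analysis assumes, including a
tunable abnormal-synergy coupling knob. Every stage of the pipeline is
therefore testable end to end without patient data.

## The model

### From load cell to joint torques

The load cell reports forces $F$ and moments $M$ at its own origin. For a
joint centre at lever arm $r$ (in the load-cell frame) the anatomical
joint moment is

$$ m = R\,(M + r \times F), $$

with $R$ the rotation from the load-cell to the anatomical frame. Three
of the four torque DOFs (AB/AD about the sagittal axis, ER/IR about the
humeral long axis, HAB/HAD about the vertical) are components of the
shoulder moment; elbow flexion/extension is a component of the elbow
moment. A single 3-component joint moment cannot carry four independent
DOFs, so the geometry object holds *two* lever arms (load cell to
shoulder, load cell to elbow) and an `axis_map` assigning each DOF a
(joint, component, sign). The default geometry encodes the standard
posture — arm in the transverse plane at shoulder height, elbow flexed
90° — with the humerus along the anatomical y axis.

The transform is linear in the wrench and invariant to the lever arm for
a pure couple; both properties are tested. The generator uses the exact
algebraic inverse of this transform, so synthetic load-cell channels
round-trip to the latent joint torques at machine precision when torque
noise is off.

### Preprocessing

* **Notch filtering.** Mains interference is removed with 6th-order
  Butterworth band-stops at 58–62 Hz and at each harmonic up to the
  450 Hz edge of the usual EMG hardware band. Offline analysis permits
  zero-phase (forward–backward) application; odd-reflection padding of
  about 2 s suppresses edge transients. The filter attenuates a 60 Hz
  tone by more than 30 dB while changing a 35 Hz tone by well under 1 dB,
  and passes DC to within $10^{-6}$.
* **MVT.** The maximum voluntary torque of a trial is the peak of the
  *trailing* 200 ms moving average of the primary-direction torque
  (rectified toward the tested direction). Trailing alignment is chosen
  because it is the online-capable convention; the alignment choice only
  shifts the reported index, not the peak value, for sustained efforts.
* **Trial selection.** Of the 3–6 trials per direction, the three with
  the largest MVT are retained (ties broken toward earlier acquisition).
  The protocol's stop criterion — top three within 10% and the last trial
  not strictly the greatest — is evaluated and reported as a flag but
  never blocks analysis.
* **Segmentation.** Samples where the raw rectified primary torque
  strictly exceeds 20% of the trial's MVT form the active segments. The
  comparison uses the raw torque against the smoothed-derived MVT: the
  threshold rule is about which *samples* carry task information, while
  MVT is a strength summary; smoothing the comparison signal would shift
  segment edges by up to half a window. Runs shorter than one analysis
  window stay in the segment list but produce no windows.

### Features and classifier

Windows are 200 ms long with a decision every 25 ms (175 ms overlap);
windows never span the gap between active runs, and a trailing partial
window is dropped. Four feature sets are computed from identical window
partitions:

| set | dimension | content |
|---|---|---|
| `EMG_TD` | 32 | Hudgins time-domain features (MAV, zero crossings, slope-sign changes, waveform length) per EMG channel, channel-major |
| `LOADCELL` | 6 | window mean of each raw load-cell channel |
| `TORQUE` | 4 | window mean of each joint-torque DOF |
| `EMG_LC` | 38 | `EMG_TD` followed by `LOADCELL` |

The zero-crossing and slope-sign-change counts accept an amplitude
deadband (default 0, i.e. off); zeros are treated as positive so
stretches of exact zeros never generate counts on their own.

The classifier is LDA with class means and a single pooled within-class
covariance estimated with $N - K$ degrees of freedom. Scores are the
usual Gaussian discriminants
$x^\top S^{-1}\mu_k - \tfrac12 \mu_k^\top S^{-1}\mu_k + \log \pi_k$,
computed through a Cholesky solve rather than an explicit inverse.
Priors default to uniform (the protocol balances trials across classes).
A ridge of $10^{-6}$ times the mean diagonal keeps the covariance
positive definite under collinear features; a covariance that is singular
even after regularization is reported as an error, never silently
repaired. Ties in the argmax go to the first class in model order so
confusion matrices are reproducible.

### Cross-validation and reporting

Validation is trial-wise: with three retained trials per class, fold $j$
trains on the other two trials of *every* class and tests on trial $j$.
Holding out whole trials prevents leakage between temporally overlapping
windows. Per-class accuracy is computed within each fold and averaged
over the three folds; the overall accuracy is the unweighted mean of the
eight class accuracies (the class-balanced convention, so classes with
slightly different window counts contribute equally). Pooled counts over
all folds populate the confusion matrix, whose rows are reported as
percentages (full precision internally; rounding only at print time).
Classes are ordered with the flexion-synergy block first (EF, AB, ER,
HAB, EE, AD, IR, HAD) so within-synergy confusions appear as diagonal
blocks. Cells at or above 90% — a commonly used usability threshold for
myoelectric control — are flagged in the summary table.

Two descriptive outputs accompany the accuracies: a scatter of
window-mean AB/AD torque against ER/IR torque (each normalized by the MVT
of the direction matching its sign) for the four rotation/ab-adduction
classes, which visualizes coupled task strategies; and Spearman rank
correlations between per-participant accuracy and the clinical scores.
The rank correlation follows the textbook recipe — Pearson correlation of
average ranks with a two-sided $t$ approximation for the p-value, which
is approximate at small $n$; when accuracies are constant across
participants the correlation is undefined and reported as `NA` with a
note. The window means (rather than raw samples) are plotted because they
are exactly the quantities the classifier sees.

## The synthetic-trial generator

Each trial is built from a latent 4-DOF torque series: a trapezoidal
effort envelope (1 s ramp, 2 s hold at the plateau, centred in the 5 s
trial) times the class's signed torque-direction row, plus white Gaussian
torque noise (0.5 N·m). The load-cell channels are obtained by inverting
the rigid-body transform, so the preprocessing stage recovers the latent
torques exactly up to that noise. EMG channels are amplitude-modulated
band-limited (20–450 Hz, 4th-order Butterworth) Gaussian noise — the
standard interference-pattern surrogate for surface EMG — with standard
deviation `noise_floor + gain * envelope`, plus a 60 Hz mains sinusoid.

Defaults were fixed once, on physiological grounds:

* plateau torques of 14–32 N·m on the primary axis with small
  same-synergy secondary torques (each row dominated by its own axis — a
  validated invariant);
* activation gains in which adduction and internal rotation are both
  pectoralis-dominant and abduction and external rotation share deltoid
  activity, mirroring which muscles these electrode sites actually pick
  up — EMG alone is therefore deliberately less separable than the load
  cell;
* noise floor 0.01 and mains amplitude 0.02 signal units; ±5% per-trial
  plateau jitter so the 10% trial-selection rule is exercised;
* clinical scores drawn uniformly (Fugl-Meyer integer 10–45, the
  moderate-to-severe inclusion range; reach fraction in [0, 1]) with *no*
  built-in relation to signal quality, so accuracy–score correlations are
  null by construction;
* `synergy_coupling` default 0.5, a moderately impaired cohort.

The coupling knob $c \in [0,1]$ replaces the AB and ER rows (and AD and
IR) of both matrices by $(1 - c/2)\,\text{own} + (c/2)\,\text{partner}$:
at $c = 0$ profiles are unmixed, at $c = 1$ the paired rows coincide, so
those classes are indistinguishable in the mean and accuracy on them
falls toward the 50% pair-chance level. One knob drives both torque and
EMG because single-DOF tasks cannot distinguish a coupled strategy from a
mandatory synergy. Two idealized activation matrices support
benchmarking: `separable_activation()` (one dominant muscle per class;
with it an uncoupled cohort classifies at ceiling on every feature set)
and `overlapping_activation()` (nearly identical rows; with it load-cell
features clearly beat EMG and fusion does not hurt, reproducing the
qualitative ordering seen in real cohorts).

What the generator does *not* emulate: motor-unit physiology,
force–EMG nonlinearity, fatigue, electrode lift or motion artifact, and
real inter-participant heterogeneity of strategies. Passing tests
therefore demonstrate that the pipeline recovers planted structure under
its own assumptions, not that a particular clinical accuracy would be
attained; cohort-level accuracies from published studies of this paradigm
are not reproducible without the original recordings.

## Numerical and design choices

* Problem sizes in the test suite and acceptance script are kept small by
  design — cohorts of one or two synthetic participants, 2–5 s trials —
  which is ample for the structural and recovery properties being
  checked, since every trial contributes ~150 windows per class.
* The trapezoidal envelope is exactly 1 on the hold interval and exactly
  0 outside the active portion; the degenerate `ramp = 0, hold =
  duration` case is the constant envelope.
* `select_trials` interprets "the last trial is the greatest" strictly:
  an exact tie with an earlier trial does not violate the stop criterion
  (so four equal maxima satisfy it).
* Windowed features index each contiguous run independently; the window
  count per run always equals brute-force enumeration.
* The LDA oracle used in tests evaluates full Gaussian log-densities with
  an explicit `solve()` on independently recomputed means and covariance
  — a different code path from the Cholesky-based implementation — and
  predictions must match exactly on random small problems.
* Determinism: the generator consumes the R RNG linearly; a dataset is
  bit-identical under the same config and seed, and the offline analysis
  itself is deterministic.

## Limitations

The geometry is user-supplied; no anthropometric estimation is included.
EMG amplitude normalization, artifact rejection beyond the notch, other
classifiers and majority-vote post-processing are out of scope, as is any
real-time decision streaming. The p-value of the rank correlation is an
asymptotic approximation, acceptable for descriptive use at cohort sizes
of interest.
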