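---
title: "Methods: simulating and analyzing the gaze-based STM-CIT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing the gaze-based STM-CIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stmcit)
```

## The paradigm

The short-term-memory concealed information test (STM-CIT) embeds a
memory task in a concealed-information design. On each trial the
observer memorizes four simultaneously displayed faces (the *parallel
display*, 5,000 ms, a 2x2 grid of 11.5 x 8.6 degree pictures centered
at 18 degrees of eccentricity), then judges whether a probe face (the
*single-face display*, at screen center, response deadline 5,000 ms)
was among them. Half of the 64 test trials contain one famous face
among three unknown ones. Even when observers try to conceal their
familiarity, gaze during the parallel display betrays it: the familiar
face attracts fixation early (orienting, roughly the first second) and
is then relatively avoided. Two summary windows capture this: phase 1
(200-1,000 ms) and phase 2 (1,001-5,000 ms). The *preference index* per
phase is the mean signed difference between the proportion of phase
time spent on the familiar face and on the unknown faces (their dwell
pooled and divided by three); the reported group means are about +0.06
in phase 1 and -0.06 in phase 2.

The package implements the full analysis chain and, since the original
recordings are not shipped, a synthetic-data generator whose outputs
have the statistical structure the analysis assumes. Every stage is a
plain-data function: tibbles in, tibbles out.

## Trial scheduling

`generate_schedule()` builds the 64-trial design: six trial types
(counts 16/8/8/16/8/8) crossing famous-in-parallel, famous-as-probe and
the correct answer; single-gender trials balanced 32/32; each famous
face appears exactly four times in the parallel displays, once per grid
location, and four times as the probe; each unknown face appears
exactly four times in the parallel displays and at most once as the
probe. Two readings in the design were fixed as follows. With 224
unknown parallel slots and 56 unknown faces, "three or four appearances"
is only satisfiable as exactly four each under a maximum of four, so
exactly four is enforced. "Unknown faces appeared only once" as probes
is read as *at most* once (only 32 probe slots exist for types 2/3/5/6).
One constraint is added beyond the original design: every unknown face
appears at least once in a display with no famous face, which guarantees
that classification features are computable for every face (the
"unknowledgeable" observations are extracted from exactly those trials).
Generation is randomized slot assignment under per-face quota counters
with bounded restarts; `validate_schedule()` re-checks every constraint
independently and names offenders.

## The gaze generator

`simulate_participant()` renders 1,000-Hz monocular traces per trial.
The parallel-display scan path is a continuous-time Markov chain over
five states: the four picture AOIs and the background.

* The first fixation sits at screen center (the fixation-check
  procedure guarantees this), with a full lognormal duration.
* Fixation durations are lognormal with median 250 ms and sigma 0.4 —
  generator assumptions in the usual range for face viewing, not
  empirical claims of the study.
* Saccade durations follow the classic main sequence, 21 ms + 2.2
  ms/deg of amplitude, computed between AOI centers; trajectories are
  linearly interpolated.
* At each fixation end the next state is drawn with weights 1 per face
  AOI and 0.15 for the background (faces dominate gaze in such
  displays), excluding the current state. When the display contains an
  effectively familiar face, that AOI's weight is multiplied by a
  phase-specific factor: one factor before 1,000 ms and another after.
* A saccade that would outlast the display, or leave a terminal
  fixation shorter than 20 ms, never launches; the last fixation is
  held to the display offset. Events therefore tile [0, 5000] exactly,
  which makes the generator's own event log an exact oracle for the
  detector.

**Calibration.** The two multipliers are not free parameters: the user
states the target expected dwell-proportion differences `theta_orient`
(phase 1) and `theta_avoid` (phase 2), and `calibrate_bias()` solves
for the multiplier by bisection against a common-random-number Monte
Carlo estimate of the chain's expected phase dwell difference (50,000
trials per evaluation), then verifies the solution on an independent
simulation of at least 10,000 trials against a +/-0.005 tolerance. The
verification sample grows until its own Monte Carlo standard error
supports that tolerance, so a correct solution is not rejected for
sampling noise. Phase 1 is calibrated first (its dwell cannot depend on
the post-1,000-ms multiplier); phase 2 is calibrated conditional on
the phase-1 multiplier, because the state occupied at 1,000 ms depends
on phase-1 dynamics. Results are cached per configuration. The same
chain core drives calibration and the full generator, so calibrated
expectations transfer exactly. Defaults are the reported group means,
+0.06 and -0.06.

**Noise model.** The nominal positional noise of 0.3 degrees is
implemented as a constant per-fixation offset (landing scatter plus
slow drift) around the AOI center, with an additional per-sample
tremor of 0.005 degrees. The fixation-level reading is deliberate:
independent 0.3-degree noise at every 1,000-Hz sample would pass
through the five-point differentiator as roughly 285 deg/s of velocity
noise and ~90,000 deg/s^2 of acceleration noise — two to four orders of
magnitude above the 30 deg/s and 8,000 deg/s^2 parsing thresholds — and
no velocity-based parser could operate. Real high-speed eye trackers
show exactly this split: accuracy errors of a few tenths of a degree
that are nearly constant within a fixation, and sample-to-sample
precision noise well below 0.05 degrees.

**Blinks** are Poisson per trial (default rate 0.2) as 100-300 ms runs
of invalid samples inserted at fixation onsets. **Behavior**: the probe
response is drawn from the reported single-face statistics — reaction
times Normal(1005.5, 187.8) ms for familiar and Normal(1288.7, 225) ms
for unknown probes, accuracies 0.97 and 0.87, no-response probability
0.0046. **Post-test judgments** flip famous faces to "unknown" with the
miss rate and unknown faces to "famous" with the false-recognition
rate (defaults 0.01 each, chosen so that the per-participant
proportions of affected trials fall in the low-percent range reported
for such tests). The gaze bias follows the participant's *effective*
familiarity — the post-test judgment — so a falsely recognized face
attracts and repels gaze like a truly familiar one, which is the
premise of the relabeling analysis.

An optional `bias_mechanism = "duration"` rescales fixation durations
on the familiar face instead of transition weights; it is off by
default because the index is dwell-based and the transition mechanism
is the simplest one whose expectation can be calibrated directly.

## Event detection

`detect_events()` re-implements a vendor-style kinematic parser: speed
from five-point central differences per axis (one-sided at the ends),
acceleration as the central difference of speed, and a saccade as a
maximal run of samples exceeding 30 deg/s *or* 8,000 deg/s^2, with a
4-ms minimum duration. Acceleration transients at motion corners extend
such a run by the stencil width of the differentiator, so run
boundaries are refined to the outermost above-velocity-threshold
samples when any exist; detected boundaries then agree with the
generator's event log within 2 ms on noiseless traces. Blinks are
maximal invalid runs padded by 50 ms on each side and merged when the
padded intervals overlap. Fixations are the complement of saccades and
blinks; each fixation's AOI is the picture box containing its centroid
(inclusive edges), and background fixations are retained but flagged as
excluded. The thresholds, minimum duration and padding are exposed as
arguments; the original study's vendor parser does not document its
smoothing, so these are stated assumptions — the calibrated quantities
the acceptance checks depend on are phase dwell *differences*, which
are insensitive to symmetric boundary conventions.

## Features

Per trial and phase, dwell is the overlap of AOI fixations with the
phase window; the three unknown faces are pooled and divided by three.
A fixation spanning the 1,000-ms boundary splits its dwell by overlap
while its *count* is credited to the phase containing its onset (the
conservative reading that keeps dwell exact and counts unambiguous);
gaze before 200 ms counts toward neither phase, though the 50-bin time
course plots from display onset. Proportions are taken against the
phase duration (800 / 4,000 ms), so background time depresses famous
and unknown proportions symmetrically. A *visit* is a maximal run of
consecutive fixations on one picture; background fixations break runs,
since a saccade to the background leaves the picture. Per-face feature
vectors (phase-1 dwell, phase-2 dwell, total fixation count over the
full display, total visits) aggregate as the *mean* per qualifying
appearance — a sum would confound the appearance counts, which differ
between familiar faces (four famous-trial appearances) and unknown
faces (only their no-famous-trial appearances qualify).

Misidentification relabeling follows the post-test: false recognitions
become familiar, misses become unfamiliar; displays with more than one
false recognition, or a celebrity plus a false recognition, are
excluded, and a strict mode drops every trial containing any
misidentified face.

## Inference

`location_test()` gates a one-sample t-test behind Shapiro-Wilk at
alpha .05, falling back to an (exact, when possible) Wilcoxon
signed-rank test. `mixed_anova()` is the classical sums-of-squares
mixed ANOVA (between: group; within: phase) with partial eta squared
per effect; sphericity needs no correction with two within levels.
`tukey_posthoc()` compares all 15 pairs of the six group-by-phase cells
through estimated marginal means with studentized-range adjustment;
"families of 15 estimates" is read as exactly these pairwise cell
comparisons. Bayes-factor analyses are out of scope; the frequentist
table is the package's inferential product.

## Classification

The protocol is an RBF-kernel SVM over the 64 per-face feature vectors
(8 familiar vs 56 unknown), C and gamma each searched over
10^-3 ... 10^3, with standardization statistics always estimated on the
training partition in use and applied to its test partition.
Within-participant evaluation is *nested* by default: a stratified
4-fold outer split (16 images per fold, 2 familiar each) provides
held-out images, and hyperparameters are chosen by an inner stratified
3-fold grid search on each outer training set. Nesting honors both
requirements the protocol states — a genuine train/test separation and
a 4-fold grid search — which a single 4-fold loop cannot do at the same
time; the single-level reading remains available via `nested = FALSE`.
Decision scores pooled over the outer folds give one ROC AUC per
participant; pooled hard predictions give balanced accuracy and F1.

F1 is implemented as the harmonic mean of sensitivity (recall) and
precision. The protocol's text description ("specificity and
precision") contradicts the standard definition and the reference
implementation it names; the standard definition is used.

Grid selection scores folds by plain accuracy by default, mirroring
the reference implementation's default scorer, and this choice is
load-bearing at both ends of the performance range. Under random
taggings no hyperparameters beat the 56/64 base rate, the selected
model collapses to the majority class, and the baseline F1 is exactly
zero with zero variance — the protocol's reported chance behavior, and
the only mechanism that produces it. On separable features,
accuracy-tied models all classify correctly, so the selected model's
hard predictions are good. An AUC scorer (`score = "roc_auc"`) is
available but subtly degenerate: on separable data dozens of grid
points tie at AUC 1 and the stable tie-break lands on the smallest,
most regularized entry, whose hard predictions revert to the majority
class even though its decision scores rank perfectly. No class
weighting is applied in either mode.

The random-tag baseline redraws, per participant, a uniform 8-of-64
famous tagging (fresh draw per participant per run) and reruns the
identical procedure; `compare_to_baseline()` applies Welch two-sample
t-tests per metric with Cohen's d on the pooled SD.

## Problem sizes and reproducibility

The simulation-based checks use one 64-trial schedule and 15
simulated participants per cohort — the study's per-group sample
size — and the calibration uses 50,000-trial Monte Carlo evaluations;
property suites run on single participants or on the chain core
directly, where 100,000+ trials are cheap. Every stochastic stage
derives its stream from one master seed via `substream_seed()`, and
identical inputs give bit-identical outputs, which the tests assert.

## What the synthetic cohort does and does not show

Passing checks demonstrate that the pipeline recovers, from raw
synthetic samples, the quantities the generator was calibrated to
produce (phase dwell differences, chance-level baselines,
design constants), and that every stage honors its contract. They do
not certify performance on human data: a first-order Markov chain has
no inhibition of return, no stereotyped scanning order, no pupil or
head-movement artifacts, and its per-trial dwell variance is large
relative to a 0.06 mean contrast. One consequence is worth stating
plainly: with effect sizes set to the reported group-mean preference
indices, within-participant classification of the synthetic cohort
reaches mean ROC AUCs around 0.6, far below the perfect discrimination
reported for human observers. Real scan paths evidently carry
participant-consistent structure (strong, brief orienting; stereotyped
avoidance) well beyond what the phase-averaged dwell contrast
summarizes, and a chain calibrated only to that contrast cannot
reproduce it. The classification machinery itself verifies on
construction: fully separated synthetic features yield AUC = 1, random
taggings sit at chance with collapsed F1.

## Known limitations

* The generator models neither microsaccades, smooth pursuit, drift
  correction, nor pupil dynamics; single-face scanning is one-AOI by
  construction.
* The detector is a velocity/acceleration parser without dispersion
  fallback; very slow drifts below 30 deg/s are never saccades.
* Between-participant classification assumes feature tables are
  comparable across participants after training-set standardization;
  no further harmonization is applied.
* Bayesian model comparison for the ANOVA family is deliberately not
  implemented.
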