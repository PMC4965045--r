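---
title: "Models, defaults and numerical choices in fnirsbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, defaults and numerical choices in fnirsbci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsbci)
```

# Scope

`fnirsbci` implements a per-second, closed-loop fNIRS classification
pipeline for bilateral hand movement — feature extraction, Parzen-window
mutual-information channel selection, an adaptively retrained linear
SVM with rest-bias correction, and thermometer neurofeedback — plus a
synthetic data generator that stands in for the recordings such a
system consumes. This vignette is the package's own account of the
models, the tunable parameters and their defaults, the numerical
choices, and the places where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

# Montage and protocol

Optodes alternate emitter/detector roles in a checkerboard; each
horizontally or vertically adjacent pair forms one channel, so an
`r` × `c` grid yields `r(c−1) + c(r−1)` channels and two 4×4 grids
yield the default 48 (24 per hemisphere, grid 1 over C3/left, grid 2
over C4/right). Two conventions were not machine-recoverable from the
source material and are fixed here: the corner position (1, 1) is an
**emitter** (this only relabels roles, not geometry), and channel
indices run grid-major, then by emitter position row-major, then by
detector position.

A run is six task blocks (three left, three right, order drawn as a
seeded uniform balanced permutation) separated by seven rest blocks.
Block durations are configurable; the defaults of 20 s task / 20 s rest
give the hemodynamic response time to rise (3–5 s) and return toward
baseline within each cycle. The three experiment designs are encoded in
`experiment_plan()`: subject-dependent ME (runs 1–2 train), subject-
dependent MI (run 1 trains), and the subject-independent design in
which a frozen pooled classifier is supplied externally and feedback is
on in every run.

# The synthetic world

`generate_run()` builds, per channel,

HbO(t) = evoked(t) + oscillations(t) + drift(t) + noise(t)

with every stochastic term drawn from one seed (identical inputs give
byte-identical output).

## Evoked response

The kernel is a unit-peak double gamma: a gamma density with unit rate
and mode at `peak_delay` (default 5 s), minus an optional undershoot
gamma (mode `undershoot_delay`, default 15 s) scaled by
`undershoot_ratio`. The undershoot **defaults to 0**: it is optional in
this model and post-stimulus HbO undershoots in adult motor fNIRS are
weak and inconsistent; a nonzero ratio is one parameter away.

The neural drive behind a 20 s task block is neither a pure sustained
boxcar nor a pure onset impulse, and the choice matters because the two
natural extremes each contradict an observed property of the system
being emulated:

* a **pure boxcar** drive convolved with the kernel keeps rising until
  the kernel's integral peaks, putting the output maximum ~10 s after
  the cue — far later than the 3–5 s latency the per-second classifier
  output exhibits;
* a **pure impulse** (fully adapting) drive leaves the last ~8 s of
  each block with no discriminable signal, capping per-second ME
  accuracy around 73% — below the ~80% regime the generator is
  calibrated to reproduce.

The implemented drive is therefore a mixture: an onset transient (the
kernel itself, modelling the strong initial engagement and rapid
adaptation of repetitive ~1 Hz clenching) plus a `sustain` fraction
(default 0.2) of the boxcar-convolved response. The evoked output rises
to its peak just after `peak_delay` and then decays to a positive
plateau (~45% of peak) for the rest of the block, which simultaneously
yields the 3–5 s latency and block-long discriminability. `sustain = 1`
recovers the pure boxcar world; `sustain = 0` the fully adapting one.

## Spatial structure

A compact "motor area" — the `active_channel_fraction` (default 0.25,
i.e. 6 of 24) channels whose midpoints lie nearest the grid centre —
carries the response in the hemisphere **contralateral** to the cued
hand at gain `contra_gain` (1.0); the homologous ipsilateral set
responds at `ipsi_gain` (0.3, the weaker ipsilateral engagement of
unimanual movement). Motor imagery differs from execution in two ways:
every response is scaled by `mi_gain` (0.6) and the active set is
shifted one optode spacing anteriorly and broadened by two channels,
reflecting the more anterior, less focal activations imagery produces.
HbR mirrors HbO inverted at `hbr_ratio` (0.3) of its amplitude, lagged
by `hbr_lag` (1 s).

Per-subject variability (`generate_subject()`): the active-area target
jitters by up to **half** an optode spacing (±12.5 mm) per axis and
amplitudes scale by U(0.8, 1.25). Half a spacing, not a full one, is
deliberate: ±25 mm displaces the compact 6-channel active set onto
entirely disjoint channels for some subjects (measured overlap of zero
with any pooled subject's set), which no pooled classifier could
bridge, and is well beyond the ~1 cm scale of real inter-subject
motor-cortex localization variability; at ±12.5 mm a pooled
subject-independent model transfers to held-out subjects reliably, as
the acceptance suite verifies.

## Nuisance terms and calibration

Physiological oscillations are channel-random-phase sinusoids: Mayer
waves (0.10 µM at 0.10 Hz), respiration (0.05 µM at 0.30 Hz), cardiac
pulsation (0.05 µM at 1.0 Hz — mostly averaged out by the one-second
feature sums). Drift is linear with a per-channel slope uniform in
±`drift_slope` (0.002 µM/s). Measurement noise is white with
`noise_sd` per sample.

Absolute effect sizes were never tabulated for the system being
emulated, so amplitudes are anchored at `hbo_amp` = 1 µM (a typical
motor ΔHbO) and `noise_sd` was **calibrated by simulation** — the one
dial the generator's contract says to set this way — so that the
default world yields ~80% online ME accuracy for a subject-dependent
model (train run 1, stream run 2). The sweep over
`noise_sd ∈ {0.30, 0.40, 0.45, 0.60, 0.80}` gave mean ME accuracies of
roughly 90, 82, 81, 74 and 75%; the frozen default is **0.45 µM**
(ME ≈ 81%, MI ≈ 76%). Timestamps are exactly `j/fs` at `fs` = 7.69 Hz;
nothing is resampled.

## What the generator does not emulate

Motion artifacts, optical-density/Beer–Lambert physics, serially
correlated (1/f) noise, systemic confounds shared across channels,
learning or fatigue effects under feedback (the closed loop does not
alter the signal), and curved-scalp geometry. A green accuracy test
therefore establishes that the *pipeline* recovers the structure this
world contains — lateralized, HRF-shaped, noisy responses — not that it
would survive every artifact of real recordings.

# Feature extraction

`f_n(k)` sums the HbO samples with timestamps in `[k−1, k)`. At the
non-integer 7.69 Hz rate a window holds 7 or 8 samples (769 over
100 s); summing whatever falls in the second preserves the intended
"sum over one second" semantics without resampling. Each feature vector
carries the block label at its window start. Seconds are counted from
run start; block onsets map them to within-trial time. Features are
linear in the signal and additive across channels, properties the test
suite asserts directly.

Only task seconds with left/right labels enter class-conditional
estimation and SVM training; rest seconds are excluded (labels are
strictly binary), but their decision values drive the bias correction.

# Channel selection

Mutual information is computed **per channel** (best individual
feature): `I = H(ω) − H(ω|F)` with class priors from label frequencies,
Gaussian-kernel Parzen class-conditional densities, and `H(ω|F)`
approximated by the sample average of the posterior entropy. Numerical
choices:

* **bandwidth** per class by Silverman's rule (`stats::bw.nrd0`), with
  a floor of `max(sd · 1e−3, 1e−12)` so constant features yield MI = 0
  rather than NaN;
* the estimate is clipped to `[0, H(ω)]`;
* for very large samples the kernel sums use an evenly thinned
  reference subset of ≤ 800 points per class — a cap on the quadratic
  cost that is statistically invisible at the package's sample sizes
  (the largest pooled fit, 12 runs, stays under it per class).

Selection keeps the `N/2` highest-MI channels **per hemisphere**
(default N = 12, 6 per side), ties broken toward the lower channel
index so selection is a pure function of the within-hemisphere ranking.

# Classifier

The canonical soft-margin linear SVM: minimize `½‖W‖² + C Σ ξ` subject
to `y_k (W'S_k − b) ≥ 1 − ξ_k`, decision `W'S − b`, boundary assigned
to "right" (the ≥ convention). The margin constraint is written here
with the canonical unit margin; the source formulation prints the bound
with the same symbol as the bias, which is treated as a typographical
artifact. `C` defaults to 1 and is exposed in the configuration.

The dual is solved exactly by sequential minimal optimization with
maximal-violating-pair working sets and second-order partner selection
(the LIBSVM strategy); a pair that cannot move is excluded until
progress resumes, which handles coincident points and degenerate
(noise-free, rank-deficient) inputs. The stopping tolerance defaults to
1e−3 (the usual practical rule); at `tol = 1e−8` the solver matches an
independent KKT-enumeration quadratic-program oracle to 1e−6 in
objective and weights on small problems, which the acceptance suite
checks. When no free support vectors remain, the bias is the midpoint
of the KKT-feasible interval.

## Adaptation and bias correction

Between runs: the model for run 2 is trained on run 1; from run 3 on,
on the two preceding runs. Training provenance is recorded in the model
and `run_online_session()` refuses to score a run the model was trained
on. For pooled subject-independent models, provenance is scoped per
subject (`1000·subject + run`) so the guard is not spuriously triggered
by run-index collisions across subjects.

Within runs: the bias offset for each task block is the mean decision
value of the **immediately preceding rest block** (the most literal
reading of the rule; not a running average), including the run's first
task block, which uses the leading rest block. The correction is
applied at test time only, never during training-set construction — an
open point resolved in favour of the simpler semantics. It is a pure
shift: within-block rankings are unchanged.

# The session loop

Each elapsed second is processed in order: rest seconds accumulate
decision values for the next block's bias; task seconds emit a
bias-corrected classification, update accuracy bookkeeping (accuracy is
the percentage of **task** seconds correct; rest is never scored — the
first scored second is the first full second after cue onset), and step
the thermometer (±1 per correct/incorrect, clamped to ±10 — a 20-level
dynamic range — reset to 0 during rest and at block end). Replaying a
recorded run through the loop is exactly equivalent to batch
application of the same model with per-block biases, an invariant the
tests assert. Feedback is display-only: the synthetic subject's signal
does not change under feedback, since modelling operant learning is out
of scope.

## Peak-latency readout

The per-second output localizes the decision peak only to a one-second
window. `decision_peak_latency()` averages the bias-corrected decision
magnitude across task blocks aligned to cue onset, smooths the 20-point
trace with a `[1, 2, 1]/4` kernel, finds the first window reaching 90%
of the smoothed maximum (a fractional-peak latency — the standard
robust readout for noisy averaged traces, since the raw argmax of a
six-block average flips by ±1 window in roughly a quarter of seeds),
and reports the whole seconds elapsed before that window begins: "the
output peaks after n seconds". In the default world this lands at
4–5 s, consistent with a kernel peaking at 5 s measured on a 1 s grid.

## Evaluation

ROC curves sweep all observed thresholds ("right" = +1 positive), AUC
by trapezoid, and the operating point is the (FPR, TPR) realized at the
deployed threshold of zero. Five-fold cross-validation splits **task
seconds** at the sample level by default — mirroring the online
pipeline's verbatim procedure — which leaks temporal autocorrelation
between folds and therefore flatters accuracy; `by_block = TRUE`
switches to a whole-block split for a leakage-free estimate. The
channel t-map (a lightweight stand-in for a full univariate GLM
analysis, which is out of scope) tests per-second **mean** HbO (window
sums normalized by their 7/8 sample counts, so the non-integer rate
adds no spurious variance) task-vs-rest per class with Welch t, flagged
at a Bonferroni-adjusted level; constant channels yield NA.

# Preprocessing (offline path)

The real-time loop runs on raw concentration changes — the streaming
schematic has no online filtering, and the classifier-level bias
correction absorbs slow offsets — while the offline path conditions
the signal in the order baseline → pre-color → detrend (the original
order of the last two steps is not recoverable; this one is fixed and
configurable):

* **baseline correction** subtracts the per-channel mean over a window,
  by default the rest block preceding each task block;
* **pre-coloring** convolves with the canonical HRF normalized to unit
  sum (unit DC gain; Nyquist content crushed well below 10%), causal
  "same" alignment with the truncated kernel renormalized over its
  available support near the series start so constants pass unchanged;
* **wavelet-MDL detrending** uses a periodized db4 pyramid transform
  (implemented in-package — no wavelet library ships with the target
  environment) after reflection padding to a power of two, depth
  `⌊log2 n⌋ − 4`. The cited detrending technique is not specified in
  detail anywhere accessible, so a minimal two-part MDL variant is
  implemented and documented as such: candidate trend models are
  "none", "coarsest approximation", "approximation + coarsest detail";
  each is scored `1.5·k·log2(n)` bits for its k coefficients plus
  `(n/2)·log2(RSS/n)` for the residual, and the winner's reconstruction
  is subtracted. At the default depth the trend band tops out near
  `16·fs/n` Hz, so a 300 s linear drift loses > 95% of its energy while
  a 0.1 Hz oscillation passes within 20% — both asserted by tests,
  along with near-idempotence.

# Configuration, I/O, reproducibility

Runs serialize to plain CSV (`time_s, block, label, ch01_hbo, …,
ch48_hbr` at full double precision) with a JSON sidecar (rate, layout
geometry and hash, generator parameters, seed, schedule); write-then-
read reproduces the series to float text precision and all metadata
exactly, with format errors (missing sidecar, channel-count mismatch,
empty file) reported as typed conditions, not crashes. Configuration is
JSON (no YAML parser is available in the target environment); unknown
keys are rejected and every validation error names the offending key.
Every stochastic stage takes an explicit seed and restores the caller's
RNG state, so equal configuration plus seeds gives byte-identical
outputs.

# Known limitations

Single-channel (marginal) MI ignores channel interactions by design;
the accuracy-versus-N characterization is out of scope. The SMO solver
is plain R — adequate for this problem scale (worst case here: 1440 ×
12), not for orders of magnitude more. Sample-level CV leaks (see
above). The generator's nuisance model is deliberately simple; claims
about robustness to motion artifacts or systemic physiology are not
supported by these tests. Latency is reported at 1 s resolution, the
native resolution of the per-second loop.
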