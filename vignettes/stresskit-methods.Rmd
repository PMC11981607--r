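---
title: "stresskit: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stresskit: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresskit)
```

stresskit implements the bespoke quantitative procedures used in chronic
stress / hyperarousal studies of rodents — fiber-photometry transient
analysis, trajectory-based behavioral event detection, startle/PPI
quantification from pose keypoints, pupillometry, and slice
electrophysiology feature extraction — together with synthetic-data
generators that produce every input type with known ground truth. This
vignette is the package's own account of the underlying models, the
parameters that matter, and the choices made where the published procedures
leave details open.

## Fiber photometry

### Model and assumptions

Two channels are acquired simultaneously at 1017 Hz: a calcium-dependent
signal F465 and a calcium-independent isosbestic control F405. Both share
slow photobleaching and motion artifacts; only F465 carries calcium
transients. The control is fitted with a degree-2 polynomial in time
(configurable; degree 2 captures monotone decay with curvature), and

$$\Delta F/F = \frac{F_{465} - \hat F_{405}}{\hat F_{405}}$$

where $\hat F_{405}$ is the *fitted* curve. Using the fitted rather than
the raw control as denominator keeps control-channel noise out of the
ratio; the subtraction in the numerator matches the convention of removing
the fitted control from the signal channel. Note an important property of
this correction: because the control is fitted *against time*, only slow
decay is removed — any fast shared motion artifact passes through to
ΔF/F untouched. The method is therefore only appropriate for
well-coupled, low-motion preparations, and the synthetic generator's
default motion level is chosen accordingly (see below).

### Baseline and transient detection

A baseline segment of duration drawn uniformly from 5–10 s provides the
mean μ and standard deviation σ; samples strictly exceeding **μ + 3σ**
("exceeding" is strict: a maximum exactly at threshold is not an event)
form maximal runs that become transients, each characterized by its peak
time and amplitude.

Two details are deliberate design choices:

* **Baseline selection.** `select_baseline()` draws `n_candidates = 20`
  seeded uniform candidate windows and keeps the one with the lowest mean.
  A baseline segment is by definition transient-free, and transients can
  only raise a window's mean, so the lowest-mean candidate operationalizes
  "a randomly selected baseline segment" without manual curation — while
  staying fully seeded and deterministic. With a single candidate the
  function reduces to a pure uniform draw (used by the sampling
  distribution tests). Selecting on the *standard deviation* instead would
  bias σ low and flood the detector with false events; selecting on the
  mean leaves σ an honest estimate of baseline fluctuation. With plain
  uniform draws, windows that happen to contain transients inflate σ (by
  Campbell's theorem the inflation grows with event rate), pushing the
  threshold toward the transient peak amplitude and collapsing
  sensitivity at physiological event rates — which is why a detection rule
  quoted as "μ + 3σ of a baseline segment" must mean a segment that is
  actually baseline.
* **Event post-processing.** Runs separated by less than
  `merge_gap_s = 0.02` s (about twice the noise correlation time) are
  merged — this reunites noise-fragmented runs of a single transient
  without bridging distinct transients of a fast indicator. Events whose
  total supra-threshold time is below `min_duration_s = 0.03` s are
  discarded; the duration criterion counts supra-threshold samples only
  (not the merged span), so two brief noise blips bridged by a merge gap
  cannot masquerade as one long event. A 5σ transient with the default
  kernel stays above a ~3σ threshold for roughly twice that minimum.

The published "amplitude" of a transient is not defined precisely;
`detect_transients()` defaults to peak ΔF/F minus μ (which reduces to peak
height when μ = 0) and exposes raw peak and peak z-score via the
`amplitude` argument. σ = 0 baselines are flagged rather than silently
re-drawn: degenerate data should be visible, and the caller can re-seed.

Session z-scores use the whole-session mean and SD; peri-event matrices
extract windows `[-pre_s, post_s]` around event times (column 0 at the
event), dropping and counting events whose windows leave the trace.
Intervals are half-open `[onset, offset)` seconds throughout the package.

### The synthetic generator

`simulate_photometry()` builds both channels from a shared single
exponential bleach (τ = 600 s) and a shared slow (< 2 Hz) multiplicative
motion artifact, adds double-exponential transients only to the 465 nm
channel, and band-limited Gaussian measurement noise to each channel
independently. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `tau_rise_s`, `tau_decay_s` | 0.01, 0.15 s | kinetics of the fast GCaMP8 indicator family used for this kind of recording; an order of magnitude faster than classic GCaMP6s |
| `transient_amp` | 5 (× noise σ) | transients clearly above the noise floor, as required for a μ+3σ rule to be meaningful |
| `noise_bw_hz` | 50 Hz | photometry front-ends low-pass their streams; genuinely white noise at 1017 Hz would make any per-sample threshold rule meaningless |
| `motion_sd` | 0.0005 (×baseline) | a clean, well-fixed preparation; the time-polynomial correction removes *no* motion, so the method itself presumes motion well below the transient amplitude |
| `bleach_tau_s` | 600 s | slow decay visibly curving over a 2-minute session |

The generator emulates shared bleaching/motion, channel gains, Poisson
event times and band-limited noise. It does **not** emulate hemodynamic
contamination, indicator saturation/nonlinearity, wavelength-dependent
artifact gain, or discontinuities from patch-cord handling — so passing
recovery tests demonstrate correctness of the pipeline's arithmetic and
detection logic under the stated noise model, not robustness to every
artifact real recordings can contain.

## Trajectory analysis

Positions are in mm with the origin at the arena center (x rightward,
y upward); frames map to times at frame centers. Arenas are hard-coded
from the standard bench dimensions: a plus maze with two open and two
closed 250 × 50 mm arms around a 50 × 50 mm center, a 500 × 400 mm open
field (center = middle half of each side), and two/three-chamber
partitions of the same floor.

Speed is computed by centering a `smooth_window_s = 0.2` s moving average
on each coordinate and differentiating centrally (endpoints replicated) —
tracking jitter at 30 fps otherwise dominates the derivative. Zone
assignment is point-in-polygon (`mgcv::in.out`); points outside every zone
are assigned to the nearest zone and counted with a warning. An *entry* is
a transition into a zone lasting at least `min_dwell = 3` frames.

Event definitions (all thresholds exposed in the function signatures):

* **Fast running** — maximal runs of smoothed speed strictly exceeding
  400 mm/s, minimum duration 0.25 s, merged across gaps < 0.2 s. The
  400 mm/s cutoff is the standard printed threshold; strictness at the
  boundary is preserved (exactly 400 does not count).
* **Center pause outcomes** — a pause is speed < 20 mm/s for ≥ 0.5 s
  inside the center; the outcome is labeled by the next arm entered, and
  the exit bout is classed run vs walk by whether its peak speed reaches
  400 mm/s. The pause parameters are unpublished conventions; they are
  package defaults, not reported constants. Events are timestamped at exit
  onset so they can anchor peri-event photometry alignment.
* **Open→closed transitions** — every open-arm → closed-arm crossing
  (through the center) yields one directional event labeled run/walk by
  bout peak speed; closed→open crossings are not emitted. Bouts extend
  into the destination arm while the animal keeps moving, so a dash's
  peak is not truncated at the zone line.

The run/walk boundary reuses the 400 mm/s fast-running threshold — the
only printed speed constant — to keep a single tunable.

`simulate_trajectory()` composes straight legs with trapezoidal speed
profiles (0.1 s ramps) between waypoints, routed through the maze center
so the path never leaves the arms, with dwells at an anchor between
scripted events. Every event the constructed path realizes is logged as
ground truth — including incidental ones (a transit walking back from an
open arm logs an open→closed walk; any leg exceeding 400 mm/s logs a
fast-running event) — so detectors can be held to *exact* count recovery.
The generator produces smooth noiseless kinematics by default
(`jitter_mm = 0`); it does not emulate tracking dropouts, body-part
mislabeling, rearing/grooming postures, or thigmotaxis statistics, so
recovery tests validate detector logic, not robustness to pose noise.

Pupillometry: pupil size per frame is both a diameter (mean of the two
opposing-point distances) and an ellipse area, since the published "size"
metric is ambiguous; series are normalized to the pre-stimulation mean and
sampled at 5 / 15 / 25 s. Low-likelihood keypoints are interpolated up to
0.5 s gaps; longer gaps are an error naming the gap.

## Startle and prepulse inhibition

The schedule follows the published protocol: ≥ 20 min baseline, ten
105 dB habituation pulses 20 s apart, then twenty PPI trials (five
pulse-only, fifteen prepulse+pulse, seeded random order) with the 75 dB
prepulse 500 ms before the pulse; both stimuli last 0.2 s. "Vibration
amplitude" is operationalized as the peak absolute displacement of each
body part from its 100 ms pre-stimulus mean position within the 200 ms
window opening at *sound onset* (the alternative — response onset — is not
used); the trial amplitude is the mean over body parts, and an RMS variant
is available. Trials whose mean body-part speed in the 1 s pre-stimulus
baseline exceeds 50 units/s are excluded, mirroring the manual rejection
of trials contaminated by spontaneous movement; the threshold is a package
default, logged with the results. The PPI ratio is the mean valid
prepulse-trial amplitude over the mean valid pulse-only amplitude and is
scale-invariant by construction.

`simulate_startle()` adds a triangular displacement impulse (peak attained
at exactly one sample, so noiseless recovery is exact) at each pulse onset
over Gaussian keypoint jitter, with optional sinusoidal whole-body drift in
designated trials to exercise the invalid-trial flagging. It does not
emulate startle habituation across trials, body-part correlation
structure, or camera distortion. For simulation economy the generators use
shortened baselines; the schedule builder's default remains the full
20 min.

## Slice electrophysiology

* **Spikes** are peaks above 0 mV separated by ≥ 1 ms
  (`pracma::findpeaks`); both constants are conventional and exposed.
* **F–I / rheobase**: spike counts for the 0–100 pA × 10 pA family;
  rheobase is the smallest step with ≥ 1 spike, absent if none. For the
  leaky integrate-and-fire generator the analytic rheobase is the smallest
  grid current *strictly* exceeding (V_th − V_rest)/R_m: at exactly the
  critical current the membrane asymptotes to threshold and never fires,
  a boundary case the simulation itself exhibits.
* **AP threshold**: voltage at the earliest sample of the contiguous
  stretch (scanning backward from the peak) where the central-difference
  dV/dt is ≥ 20 V/s. Discretization error is bounded by one sample times
  the local slope, and halving the sampling rate doubles that worst case.
  A trace whose slope never reaches the criterion is flagged `NA` with a
  warning rather than guessed.
* **Half-width**: full width at the voltage midway between threshold and
  peak (threshold-to-peak amplitude convention), with linear interpolation
  at both crossings; degenerate spikes (peak ≤ threshold) are flagged.
* **Passive properties**: the raw deflection is the mean over the last
  10 ms of the 50 ms / 5 mV hyperpolarizing step relative to the pre-step
  baseline, per the standard bench rule. Because a 50 ms step with
  τ = 10–25 ms ends 5–15 % short of steady state, the reported R is
  computed from the *asymptotic* deflection of a three-parameter
  exponential fit of the onset (profile least squares over τ: for fixed τ
  the model is linear in offset and amplitude, so the residual sum is
  minimized by `optimize()` — robust and exact on an ideal RC response,
  with no iteration or starting-value issues). Both the raw and corrected
  deflections are reported; capacitance is τ/R. The "5 mV step" phrasing
  conflates clamp modes, so both interpretations sit behind a
  `mode` flag (`current_clamp` applies the equivalent current step;
  `voltage_clamp` reads the current response).
* **Miniature PSCs**: the commercial detection package used at the bench
  does not document its algorithm, so detection here is deliberately
  simple and auditable — a 1–2000 Hz zero-phase Butterworth band-pass,
  threshold crossings in the polarity direction (inward at −70 mV for
  mEPSCs, outward at +10 mV for mIPSCs), ≥ 10 ms separation, and
  amplitude measured on the *raw* trace as the mean over ±0.5 ms around
  the detected peak minus the median of the 5 ms pre-onset baseline
  (averaging removes the upward bias of picking a noisy maximum).
* **Connectivity**: each neuron is tested for an excitatory response at
  −70 mV and an inhibitory response at +10 mV; cohort percentages are
  reported to one decimal over *responsive* neurons, matching the
  convention of a three-slice pie (both / inhibitory-only /
  excitatory-only); non-responders and neurons missing a holding condition
  are counted separately.
* **LTP**: evoked-amplitude series are normalized to
  100 × amplitude / mean(baseline), with the baseline comprising all
  sweeps up to the induction time (10 min by default); minute-binned means
  are reported at the 1st, 10th, 20th and 30th post-induction minutes. The
  baseline of the normalized series is 100 % by construction on any input.

The integrate-and-fire generator uses forward Euler at 10 kHz with a 3 ms
refractory period and a stereotyped Gaussian spike waveform pasted at
threshold crossings, so spike-shape features can be tested against template
parameters. It is not a biophysical neuron model: no adaptation,
no conductance-based synapses, no channel kinetics.

## Statistics and reporting

Group comparisons (mean ± SEM descriptives; Student's t paired/unpaired,
Mann-Whitney/Wilcoxon, one-way ANOVA with Tukey post hoc) are *delegated*
to `stats::t.test`, `wilcox.test`, and `aov`/`TukeyHSD`: these are
off-the-shelf procedures at the bench too, and the package's contribution
is the measures feeding them. `tidy()`/`glance()` methods return the
summaries and test results as tibbles.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
photometry recovery uses 120 s sessions at 1017 Hz over 20 seeds per rate
(λ ∈ {0.1, 0.3, 0.5}/s, 5σ amplitude); behavioral recovery uses 20
scripted maze sessions of ~2–3 min at 30 fps; startle uses compressed
inter-trial intervals with the full trial structure; ephys oracles use 30
random integrate-and-fire parameter draws and 10–20 seed replicates for
the stochastic recoveries. Every generator takes an explicit seed, scopes
its randomness with `withr::with_seed` (global RNG state is never
touched), and reproduces bit-identical output under a fixed seed, which
the determinism tests check at the file-byte level.

## Known limitations

The generators are calibrated to make the published procedures coherent,
not to span every recording condition: large motion artifacts defeat the
time-polynomial isosbestic correction by construction; transient detection
at rates well above ~0.5 events/s undercounts because adjacent transients
overlap within the indicator decay; the trajectory generator's kinematics
are noiseless unless jitter is requested; and the mini detector's fixed
threshold is not matched-filter optimal at low SNR. Real pose-estimation
output contains identity swaps and confidence dropouts beyond the simple
low-likelihood gaps modeled here.
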