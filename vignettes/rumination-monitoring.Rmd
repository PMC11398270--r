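---
title: "Rumination monitoring from a nose-clip sensor: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rumination monitoring from a nose-clip sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruminate)
```

This vignette documents the scientific model behind the package, the
parameters that matter, what the simulator does and does not emulate, and
the design choices made where the problem left the design genuinely open.

## The measurement model

A nose-clip respiration sensor records two things at a fixed sampling rate:
nasal differential pressure (dimensionless units; inhalation negative,
exhalation positive) and triaxial acceleration in g (full range ±1 g, the
x axis mounted so its measured value stays within ±0.25 g). During
rumination, every regurgitation leaves a two-part signature:

1. a **near-zero plateau of the z-orientation** lasting at least 2–4 s,
   produced by the head posture while the bolus is brought up, and
2. a **prolonged breath** — a wider pressure peak upward or downward —
   because the bolus is moved by inspiring against a closed glottis.

The detector operationalizes exactly this signature; the validation layer
compares its output to visual observation, the gold standard for behavior
annotation.

## Detector

`segment_breaths()` locates breath onsets at exhalation-to-inhalation
transitions: downward zero crossings of the smoothed pressure signal, taken
with a hysteresis deadband of 0.25× the median absolute pressure so that
noise near zero cannot create spurious onsets. `find_z_plateaus()` scans the
smoothed z channel for maximal runs inside the near-zero band, and
`detect_regurgitations()` accepts a plateau as an event when a prolonged
breath corroborates it.

Tunable parameters (`detector_config()`), with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `z_center`, `z_band` | 0 g, ±0.05 g | the "near 0" band. No quantitative threshold is established for this sensor, and mounting orientation varies between animals, so both are configurable; ±0.05 g comfortably separates the plateau from resting z levels while rejecting ordinary head motion. |
| `min_plateau_s`, `max_plateau_s` | 2 s, 8 s | the signature lasts at least 2–4 s; a finite upper bound rejects sustained stillness (a dozing cow is not regurgitating every breath). |
| `pause_factor` | 1.5 | a breath interval is "prolonged" when it exceeds 1.5× the **rolling median** breath interval. The rolling median (window of 9 intervals) makes the rule robust to respiration-rate drift within a recording. |
| `pause_window_s` | 10 s | the prolonged breath must begin inside the plateau or within 10 s after it. |
| `require_pause` | TRUE | plateau-only detection is available for traces whose pressure channel is unusable. |
| `refractory_s` | 20 s | suppresses double-triggering within one cycle; it must stay below the 35-s physiological minimum cycle length, which the constructor enforces. |
| `smoothing_window_s` | 0.3 s | moving-average window for both channels. |

**Event timestamp.** Events are anchored at the plateau start — the moment
chewing stops to bring up the bolus. Whether a human annotator anchors at
plateau start, center, or the pause is not standardized; the ±5 s matching
tolerance absorbs this ambiguity.

**Numerical choice: edge-erosion compensation.** A centered moving average
of width $w$ erodes a step plateau of length $L$ to an in-band run of about
$L - 0.8w$ (the smoothed value re-enters the band once ~90% of the window
lies inside the plateau). The detector therefore adds `smoothing_window_s`
back to the measured run length before applying the duration rule;
otherwise plateaus at the 2-s minimum would be systematically rejected.

**Gap handling.** Samples lost to streaming are explicitly missing, never
interpolated. Breath intervals spanning a gap are discarded, in-band runs
adjacent to a gap are dropped (they may be truncated plateaus), and no
event is ever emitted inside a gap.

## Simulator

`simulate_trial()` composes four seeded stages, each reproducible from the
configuration seed alone: breathing, regurgitation injection, distractor
motion, and streaming gaps.

* **Breathing** — a biphasic waveform per breath (half-sine inhalation,
  negative; half-sine exhalation, positive) with per-breath period and
  amplitude jitter (`period_jitter`, `amplitude_jitter`, both CV 0.1) and
  additive Gaussian noise. The default respiration rate of 30 breaths/min
  is a typical resting rate for adult dairy cows.
* **Regurgitation timing** — a renewal process with inter-event intervals
  drawn from Normal(59.27 s, 9.01 s) truncated below at 35 s. Only the
  moments of the cycle-length distribution (mean, SD, minimum) are
  established for this sensor system, not a process model; a truncated
  normal renewal process is the simplest process consistent with them, and
  truncation at 35 s matches the observed minimum.
* **The signature** — at each event the z channel is driven into the
  near-zero band for a plateau of length uniform on [2, 4] s, and the first
  breath starting after the plateau is stretched to `pause_factor` (default
  2) times the *nominal* breath period, with the extra time placed on the
  exhalation or inhalation at random. Stretching relative to the nominal
  rather than the realized breath reflects that the pause length is set by
  the regurgitation, not by whichever jittered breath happens to follow —
  and keeps the simulated pause detectable regardless of jitter.
* **Pause probability** — `pause_prob` defaults to 1.0. Descriptions of the
  signature say the prolonged breath is "often" visible, but
  physiologically every regurgitation involves the inspiratory pause; we
  read "often" as a statement about visibility in the pressure trace and
  model presence, keeping the probability configurable for sensitivity
  studies. A default below 1 would also contradict the detector's default
  `require_pause = TRUE`: the two defaults must describe the same signal.
* **Distractors** — non-rumination behavior (dozing, feeding, standing,
  lying) is emulated as brief z excursions into the band (< 1.5 s, below
  the signature minimum), longer excursions that stop short of the band
  (to 0.2 g), and half-second pressure irregularities, at
  `distractor_rate` 1/min. No quantitative description of non-rumination
  nose-sensor signals exists, so distractor realism is a modeling choice;
  what matters for validation is that distractors exercise the detector's
  rejection rules without ever satisfying the full signature. In
  ruminating trials distractors keep 10 s clear of true events.
* **Streaming gaps** — aligned to 30-s upload windows: each window
  independently loses a sub-interval (default the whole window) with
  probability `gap_loss_prob`. Continuous streaming is loss probability 0.
  The default loss probability used in streamed-trial tests, 0.35, is in
  the range implied by the observed losses (149 of 378 events, 19 of 60
  minutes).

**What the simulator does not emulate:** chew-level jaw movement and
chews-per-bolus structure, posture changes, inter-cow variability in
signature morphology, drift in mounting orientation, and correlated sensor
noise. Passing tests therefore demonstrate that the pipeline is correct
*given the signature model*, not that the detector would reach the same
performance on arbitrary field recordings.

## Validation layer

Matching is greedy one-to-one: candidate pairs within the inclusive ±5 s
tolerance are accepted in order of increasing |Δt|, ties broken by earlier
reference time. Because reference events are at least 35 s apart — more
than twice the tolerance — each sensor event can match at most one
reference event, the match graph is a union of stars, and the greedy rule
provably attains the exhaustive optimum (maximum pairs, then minimum total
|Δt|); the test suite verifies this against a brute-force oracle. Surplus
sensor events near one reference event become false positives (one-to-one
is the only defensible reading when the counting rule is unstated).

True negatives are whole event-free minutes of negative-control periods,
counted from the period start; a minute containing any sensor event is not
a TN. This whole-minute reading is the only one that reproduces a
specificity of 95.0% from 3 false positives in 60 observed minutes, which
also implies those 3 events fell in distinct minutes.

The streaming-gap correction removes from FN only the *unmatched* reference
events whose time lies inside a gap, and removes gap-affected minutes from
TN; TP and FP are untouched, so the correction can only raise Se and NPV
and lower Sp's denominator. Reported percentages are rounded half-up to one
decimal (the convention that reproduces every published cell); unrounded
ratios are retained, and an undefined ratio is reported as missing, never 0.

## Cycle statistics and rumination time

Cycle durations are successive differences within one period only — never
across periods, and never across a gap that interrupts the log. Outlier
cows are flagged by a physiological range on the per-cow mean (default
35–90 s, wide enough to keep normal cows and catch the ~2 min/cycle
pattern seen in animals with e.g. dental problems); the exact criterion
used in practice is not standardized, so flags are advisory and
recomputation without flagged cows is an explicit second call rather than
an automatic deletion.

Rumination time from discrete regurgitation events needs two conventions:
a bout rule (split where the inter-event gap exceeds `bout_gap_s`, default
180 s — about three maximal cycles) and an end-of-bout allowance for the
final cycle (default one mean cycle length, 59.27 s). Both are configurable
because on-sensor RT computation is still evolving.

## Problem sizes and numerical conventions

The package's own verification uses 10-min trials at 10 samples/s: 50
trials (≥ 400 pooled cycles) for parameter recovery, 20 clean and 20
negative-control trials for detector performance, 12 streamed trials for
the gap-correction property, and 1000 random instances for the matching
oracle. These sizes give sampling errors well inside the tolerances checked
(e.g. SE of the pooled cycle mean ≈ 0.45 s) while keeping a full run in
seconds. The sampling rate itself is a convention of this implementation —
the hardware rate is not published — chosen as the smallest rate that
cleanly resolves both individual breaths (~2 s) and the 2-s plateau
minimum; it is file-level metadata, never inferred from data rows.

Degenerate inputs follow fixed conventions: an all-missing trace yields an
empty breath series and event log; a log with fewer than two events
contributes no cycle durations; the SD of a single duration is missing, not
0; a zero denominator leaves a metric missing; gap correction that would
drive FN or TN negative is an error rather than a clamp.

## Known limitations

* The detector assumes a mounting orientation in which the plateau sits
  near 0 g; a rotated clip needs `z_center` adjusted.
* Minute-based TN counting makes Sp and NPV depend on the period
  granularity; they are comparable only between analyses using the same
  one-minute convention.
* The simulator's distractors are conservative: they test rejection rules,
  not the full diversity of barn behavior.
* Eating-vs-ruminating discrimination, chew counting and posture
  classification are outside this sensor's scope.
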