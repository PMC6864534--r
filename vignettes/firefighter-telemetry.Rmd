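---
title: "Methods: fall, incapacitation and CO alerting from wearable firefighter telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fall, incapacitation and CO alerting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firesentry)
```

## The problem

A firefighter working inside a burning structure can be incapacitated by a
fall through a weakened floor, by collapsing while crawling under smoke, by
getting stuck in a narrow path, or by carbon-monoxide exposure. Fall
detectors tuned for the elderly assume low-dynamic activity; an on-duty
firefighter runs, jumps, crawls and rides elevators, all of which produce
acceleration transients that defeat naive thresholds. This package
implements a detection stack designed around those activities: a
three-feature fall cascade, a barometer-fused loss-of-physical-performance
(LOPP) detector that tells incapacitation apart from elevator travel, and a
debounced CO alert, together with a seeded scenario simulator and an
evaluation harness.

## Signal model and conventions

The device sits in a front trouser pocket with the Az axis anti-parallel to
gravity when standing, so a resting accelerometer reads approximately
`(0, 0, 1)` g. Acceleration is stored internally in m/s²; inputs declared in
g are scaled by 9.81 at ingest. All sample indices reported in events are
0-based with `time = index / fs`, and every window length is specified in
seconds and converted through `seconds_to_samples()`, so one configuration
serves both the 100 Hz device rate and 25 Hz public-style logs. Non-uniform
time stamps are rejected rather than silently resampled, because the
detectors index arithmetically in samples; `resample_frame()` exists for
deliberate rate conversion.

The scalar feature driving both the fall gate and the quiescence gate is the
per-sample vector magnitude `Acc(t) = sqrt(Ax² + Ay² + Az²) / 9.81` in g
(conventionally called the RMS of acceleration in this field, although no
time averaging is involved; we implement the formula as stated).

## Barometric altitude and the scalar Kalman filter

Altitude comes from `H = 44330 (1 − (P/P0)^(1/5.225))` metres with
`P0 = 1013.25` hPa. The exponent denominator 5.225 is the device's
calibration constant; the common standard-atmosphere value 5.255 is
configurable (`baro_exponent_denominator`) and changes indoor-scale
differences by well under a centimetre. Two pressure readings a floor-height
apart, 890.0651 and 890.0402 hPa, differ by 0.23 m under this formula — the
scale of signal the LOPP detector works with.

The smoother is a deliberately simple scalar Kalman filter with no dynamics
model: gain `K = p/(p+r)`, state `x' = x + K (z − x)`, and uncertainty
`p' = (1−K) p + |x − x'| q`. The last term is nonstandard — process noise
proportional to how much the estimate just moved — and is implemented as
specified rather than replaced by a textbook predict step: it lets the
filter collapse its gain on a flat signal (strong smoothing at rest) yet
re-open when the signal genuinely ramps, which is exactly the behaviour the
elevator disambiguation needs. Writing the state update in the `x + K(z−x)`
form makes a constant signal a bit-exact fixed point, which the tests
assert. Defaults `r = 1 m²`, `q = 0.01`, initial `p = 1 m²`, initial
`x = first raw altitude` are package choices (the filter's parameters are
otherwise unconstrained); all are exposed in the configuration.

## Orientation: tilt angle and the Madgwick filter

Two independent orientation signals feed posture recognition:

* the tilt angle `θ = acos(Az/‖a‖)` in degrees, computed from the raw
  accelerometer by default (a config switch allows the filtered gravity
  direction instead, since either reading of the definition is defensible);
* pitch and roll extracted from the quaternion maintained by a Madgwick
  gradient-descent filter fusing gyroscope and accelerometer (and
  magnetometer when requested).

The Euler extraction uses the device's printed convention —
`Y = atan2(2q2q3 − 2q1q4, 2q1² + 2q2² − 1)`,
`P = −asin(2q2q4 + 2q1q3)`,
`R = atan2(2q3q4 − 2q1q2, 2q1² + 2q4² − 1)` — which is the conjugate of the
standard aerospace yaw-pitch-roll sequence. `quaternion_from_euler()` is its
exact inverse under the same convention, and the round-trip is tested
against that inverse, not against any other convention. Near gimbal lock the
asin argument is clamped with a warning.

Filter choices: gain `beta = 0.1` by default; the filter is warm-started
from the accelerometer tilt of the first sample (shortest-arc rotation
aligning predicted gravity with the first measurement), so posture traces
are meaningful from the start of a log. The magnetometer is *not* used by
default even when present: the posture decision consumes only pitch and
roll, which the IMU variant observes, and magnetic readings inside
steel-framed, machinery-filled buildings are exactly where hard/soft-iron
assumptions fail. The MARG variant is implemented and tested (it converges
to a fully observed static orientation including yaw) for users who want
heading.

## The fall cascade

A candidate opens at the first sample `j` with `Acc(j) > Uth` (1.8 g) and is
confirmed only if both of the following hold:

1. **Post-fall rest**: every sample in `[j + 3 s, j + 5 s]` (both endpoints
   included) lies strictly inside `(0.75, 1.25)` g. The 3 s delay lets the
   body settle after impact.
2. **Posture, double-checked**: at `j + 5 s` and `j + 5.5 s`,
   `θ > 25°` and `|pitch| > 30°` and `|roll| > 30°`, all strict. Absolute
   values are compared because falls in opposite directions produce
   opposite signs; the thresholds are stated as magnitudes.

Timing of the posture samples is a design choice: the specification of the
rest window fixes only its own endpoints, so we sample posture at the end of
the rest window and once more a re-check interval later, matching the
cascade's ordering (rest first, posture after). Three further scanning
decisions are deliberate and documented rather than inherited: (a)
super-threshold samples inside an open candidate's 5.5 s evaluation window
fold into that candidate instead of spawning new ones, so one impact is one
decision; (b) after a failed candidate, scanning resumes at the first sample
past the evaluation window; (c) after an emitted event, triggers are
suppressed for a 6 s refractory period to avoid duplicate alerts from one
impact. A trigger closer than 5.5 s to the end of the trace cannot complete
its checks and is a warned non-fall. A wearer whose angles return under
threshold before the checks — stand-up recovery — is deliberately not
alerted.

The reduced variants used for feature ablation are: `algorithm2`, single
posture check (no 0.5 s re-check); `algorithm3`, additionally no tilt
condition; `algorithm4`, no pitch/roll condition (no orientation filter).
Whenever the full cascade confirms a fall, every reduced variant must too;
the tests assert this containment on recovery fixtures. Quantitative
ablation results on recorded datasets are not reproducible without those
recordings and are out of scope; only the structural properties are checked.

## LOPP detection and elevator disambiguation

Quiescence is a maximal run in which every magnitude sample lies strictly
inside `(0.8, 1.2)` g for at least `T = 4 s`. Within each run the 4 s window
slides sample by sample; each position is classified by the Kalman-filtered
altitude change `ΔAltitude = H(j + T) − H(j)`:

* `ΔAltitude > +0.5 m` → `moving_up`;
* `ΔAltitude < −0.5 m` → `moving_down`;
* otherwise → `lopp` (motionless at fixed altitude: incapacitation).

The ±0.5 m band is applied symmetrically from the single stated threshold
(the two band edges are never given separately, and the physics is
symmetric); the acceleration bound used in the classification is the same
quiescence band — no second threshold is introduced. Consecutive windows of
the same class coalesce into one event indexed at the first window start;
sliding-with-coalescing is our documented choice where block-stepping would
also have been defensible. Without a barometer channel the elevator case
cannot be excluded, so `lopp` is still emitted, flagged `degraded`, with a
warning — silence would be the dangerous failure mode. When the fall
detector and the LOPP detector fire on overlapping samples the fall takes
precedence (the flowchart gates on the upper threshold first) and the
overlapping quiescence events are dropped.

Quiet standing genuinely satisfies the quiescence band with flat altitude —
the detection rules cannot distinguish it from incapacitation without
operational context that the method does not formalise. The package keeps
the detector honest (standing traces do produce `lopp` events) and handles
the gap at the scoring layer: the evaluation disregards `lopp` events on
standing traces, scoring standing under fall specificity only. This is a
recorded scoring decision, not hidden behaviour.

## CO alerting

The ppm trace is smoothed with the same scalar Kalman filter, then compared
inclusively against the 33 ppm alert threshold — chosen from smoke-room
measurements, below the 35 ppm occupational reference that is retained in
the config as documentation. A two-state machine with a 2 s debounce (both
our choices; the threshold comparison's inclusivity likewise) opens
`co_alert` when the smoothed level holds at/above threshold and `co_safe`
when it holds below, so events strictly alternate. `co_safe` exists so the
wearer knows when the breathing apparatus can come off to conserve air; it
is informational, never an alarm.

## The scenario simulator

`generate_scenario()` produces deterministic multichannel traces for 17
activity classes: four fall directions, crawl-then-fall, stuck-in-narrow-path,
elevator up/down, walking, running, jogging, jumping, crawling, stairs
up/down, quiet standing, and a CO exposure scenario. Construction choices:

* **Falls**: 3 s quiet stance; 0.3 s flight-phase dip to 0.3 g; half-sine
  impact peaking at 3 g; damped settling ripple; rest at 1 g. The body tilts
  75° about a horizontal axis oriented diagonally (45° between the pitch and
  roll axes, signed per fall direction) during the impact, which leaves the
  settled posture past all three angle thresholds (θ = 75°, |pitch| ≈ 43°,
  |roll| ≈ 69°). Recovery variants (`recovery_s`) rotate back upright and
  are labelled non-fall.
* **Elevator**: entry/exit transient bursts outside the quiescence band
  bracket an 11 s quiescent ride whose altitude ramps at 0.3 m/s — a slow
  constant-velocity car travelling ≈3.3 m. The ramp spans the entire
  quiescent segment so every 4 s window sees the full rate; with the default
  Kalman parameters the smallest filtered window delta is ≈0.58 m,
  comfortably above the 0.5 m band. (A ramp shorter than the quiescent run
  would leave flat quiescent windows at its edges and make the detector —
  correctly — call them LOPP; the geometry here reflects that a person stands
  still in an elevator only while it moves.)
* **Quiescence accidents**: crawling oscillation (1 ± 0.3 g), then a flat
  1 g segment with flat altitude; `crawl_then_fall` interposes a 1.5 g
  sub-threshold collapse bump.
* **Ambulatory classes**: sinusoidal magnitudes in label-specific bands —
  walking 1 ± 0.40 g (never crossing 1.8 g), jogging ± 0.55, running ± 0.90
  and jumping bursts to 2.5 g (both cross the upper threshold but never
  satisfy the post-fall rest, exercising the cascade's rejection path).
* **Orientation channels** are synthesised exactly: rotations are
  fixed-axis, so gyro rates are analytic, and accelerometer/magnetometer
  directions follow the same quaternion path — the Madgwick filter sees
  fully consistent inputs.
* **Noise**: per-axis accelerometer noise 0.02 g, barometer noise 0.01 hPa
  (≈9 cm of altitude), gyro 0.005 rad/s, CO 0.3 ppm — typical for the MEMS
  parts this class of device uses. All randomness flows from the scenario
  seed; `make_suite()` derives per-trace seeds from one master seed, so a
  suite is bit-reproducible and changing the seed changes noise
  realisations, never the truth structure.

Ground-truth indices are computed from the clean profiles before noise is
added (first upper-threshold exceedance for falls; quiescent-run starts for
LOPP and elevator classes; first at-threshold sample for CO), which makes
the clean-limit property — detector output equals truth exactly at zero
noise — hold by construction, and the tests verify it.

**What the suite does and does not show.** Passing the synthetic suite
demonstrates that the implemented rules make the intended distinctions under
the stated signal phenomenology and noise. It does not demonstrate
performance on field data: real impacts are not half-sines, real crawling is
not sinusoidal, real barometers drift with temperature and door-induced
pressure transients, and real falls can end in postures near the angle
thresholds. The suite is a correctness harness, not a validation study.

## Evaluation

Scoring is trial-level — one label per trace, matching how detection
performance is tabulated in this field — with a 2 s matching tolerance
between a truth alert and a detected event of the same kind. Alert kinds are
`fall`, `lopp`, `co_alert`; floor-direction and `co_safe` events are never
counted as alarms. Metrics are `Sen = TP/(TP+FN)`, `Spec = TN/(TN+FP)`,
`Acc = (TP+TN)/(TP+TN+FP+FN)` in percent, kept exact internally and rounded
only for display; a zero denominator yields `NA` with a warning, never 0.

The acceptance script runs the complete stack over a 340-trace suite
(20 per class, default thresholds and noise, master seed from the command
line) and reports the pooled metrics; with the defaults the stack is
error-free (TP 140, TN 200, FP 0, FN 0), the synthetic counterpart of an
error-free experimental campaign. Problem sizes throughout (trace lengths of
10–20 s, 100 Hz, 340-trace suites) were chosen as comfortably sufficient for
the windows being tested while keeping the whole suite fast to regenerate.

## Known limitations

* Threshold constants are taken as given; no per-wearer calibration or
  threshold learning is provided.
* The LOPP/standing ambiguity is real and handled by scoring policy, not
  solved.
* The barometric formula is not temperature-compensated, and the scalar
  filter has no velocity state; fast pressure transients (door slams, hose
  streams) would alias into altitude.
* Quantitative comparison against recorded public datasets requires those
  recordings and is out of scope here; only the printed worked numbers
  (the 0.23 m altitude difference, the confusion-count metrics) and
  structural properties are reproduced.
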