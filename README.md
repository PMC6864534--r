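# firesentry

Fall, incapacitation and carbon-monoxide alerting from body-worn sensor
streams recorded on duty — built for the firefighter use case, where the
wearer performs strenuous activities (running, jumping, crawling, stair and
elevator use) that defeat fall detectors tuned for the elderly, and where an
audible PASS alarm is useless amid fireground noise.

The package takes a synchronized log from a waist/pocket-mounted unit —
tri-axial accelerometer, optionally tri-axial gyroscope and magnetometer,
barometer and a CO sensor — and emits typed alert events for an incident
commander: `fall`, `lopp` (loss of physical performance), `co_alert`, plus
informational `moving_up`/`moving_down` floor-direction events.

## The detectors

**Fall cascade** (three features, all required):

1. *Upper threshold*: the g-normalised acceleration magnitude
   `Acc(t) = sqrt(Ax² + Ay² + Az²) / 9.81` must exceed `Uth = 1.8 g`
   (the impact).
2. *Post-fall*: every sample from 3 s to 5 s after the trigger must lie
   strictly inside the rest band `(Lpt, Upt) = (0.75, 1.25) g`.
3. *Posture recognition, double-checked*: at 5 s and again at 5.5 s after
   the trigger, the tilt `θ = acos(Az/‖a‖)` must exceed 25° and the
   Madgwick-filtered Euler angles must satisfy `|pitch| > 30°` and
   `|roll| > 30°`. A wearer who stands back up between the checks is not
   alerted.

Reduced variants (`algorithm2`–`algorithm4`) drop the re-check, the tilt
condition, or the pitch/roll condition, for feature-ablation studies.

**LOPP detector**: a firefighter stuck in a narrow path or collapsing while
crawling never crosses `Uth`. Instead, quiescence — every sample inside
`(Ll_mov, Lu_mov) = (0.8, 1.2) g` for at least `T = 4 s` — opens the
barometric check: the altitude change
`ΔAltitude = H(j + T) − H(j)` over the window, with
`H = 44330·(1 − (P/P0)^(1/5.225))` metres smoothed by a scalar Kalman
filter, classifies the state. `|ΔAltitude| ≤ 0.5 m` means motionless at
fixed altitude → `lopp` alert; a larger rise or drop means elevator travel →
floor-direction event, no alarm.

**CO monitor**: the ppm trace is Kalman-smoothed and compared (inclusive,
with a 2 s debounce) against 33 ppm; `co_alert` and `co_safe` events
alternate, governing when the breathing apparatus must be worn.

Evaluation uses trial-level confusion counts and
`Sen = TP/(TP+FN)`, `Spec = TN/(TN+FP)`, `Acc = (TP+TN)/(TP+TN+FP+FN)`.

## Worked example

```r
library(firesentry)

sc  <- generate_scenario(scenario_spec("fall_forward", seed = 1))
res <- run_pipeline(sc$frame)
res
#> <pipeline_result> 1200 samples @ 100 Hz
#> <detection_events> 1 event(s)
#>   kind index time_s
#> 1 fall   332   3.32
str(res$events$detail[[1]])
#> List of 5
#>  $ peak_g   : num 2.99
#>  $ theta    : num 74.7
#>  $ pitch    : num -43
#>  $ roll     : num -69.2
#>  $ algorithm: chr "algorithm1"
```

The impact at 3.32 s peaked at 2.99 g, the wearer stayed in the rest band,
and the settled posture (tilt 74.7°, |pitch| 43°, |roll| 69.2°) exceeded all
three thresholds at both checks — a confirmed fall. The same pipeline on an
elevator ride raises no alarm, only a floor-direction event:

```r
el <- generate_scenario(scenario_spec("elevator_up", seed = 1))
run_pipeline(el$frame)$events
#> <detection_events> 1 event(s)
#>        kind index time_s
#> 1 moving_up   246   2.46
```

And the metric arithmetic on published-scale confusion counts:

```r
round(detection_metrics(confusion_counts(tp = 724, fn = 31, tn = 762, fp = 0)), 2)
#>    sen   spec    acc
#>  95.89 100.00  97.96
```

A thin CLI wraps the same functions
(`inst/cli/firesentry simulate|detect|evaluate|altitude`).

## Scope

The package operates on recorded or simulated streams; radio transmission,
indoor positioning, sensor electronics and gas-sensor calibration are out of
scope. The simulator emulates the activity classes phenomenologically — see
the methods vignette (`vignettes/firefighter-telemetry.Rmd`) for what
passing its suite does and does not demonstrate about field data.
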