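Package: firesentry
Title: Fall, Incapacitation and Carbon Monoxide Alerting from Wearable
    Firefighter Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-cascade fall detection, barometer-fused loss of
    physical performance (LOPP) detection, and carbon monoxide alerting for
    body-worn sensor logs recorded from on-duty firefighters. Implements RMS
    acceleration features, a scalar Kalman smoother for barometric altitude,
    Madgwick orientation filtering with tilt/pitch/roll posture recognition
    double-checked 0.5 s apart, elevator-versus-incapacitation disambiguation
    from altitude change over quiescence windows, a seeded activity-scenario
    simulator with ground-truth events, and a sensitivity/specificity
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
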