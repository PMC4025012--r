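Package: telefall
Title: Threshold Fall Detection and Weighted-RSSI Indoor Positioning for
    Wearable Telecare
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for wearable-sensor telecare: a three-phase
    threshold fall detector for waist-worn tri-axial accelerometer
    streams (sum-vector-magnitude features, reference-velocity
    integration, cancellable normal alarms), a weighted-RSSI
    k-nearest-neighbor indoor positioning engine driven by a
    log-distance path-loss radio model, simulators that generate fall
    and daily-activity acceleration traces and RSSI collection rounds,
    and an end-to-end pipeline that localizes the wearer whenever a
    fall alarm is confirmed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
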