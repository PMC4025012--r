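# telefall

Fall detection and location awareness for wearable elderly telecare.

Falls are the leading cause of accidental injury among people over 65, and
a faller who cannot reach a phone needs two things from a telecare system:
a reliable alarm and a position to send the caregiver to. `telefall`
implements both halves of a ZigBee-style waist-worn telecare system as a
tested R library with a thin command-line front end:

* a **three-phase threshold fall detector** operating on tri-axial
  accelerometer streams sampled at 200 Hz, and
* a **weighted-RSSI k-nearest-neighbor indoor positioning engine** that a
  confirmed fall alarm triggers,

together with simulators that generate the accelerometer traces and RSSI
collection rounds both components consume, so the whole system is testable
without any hardware.

## The detector

With the sensor on the waist (x sagittal, y vertical, z frontal, in G),
the per-sample features are the sum vector magnitude and its horizontal
projection:

    SVM_xyz = sqrt(ax^2 + ay^2 + az^2)
    SVM_xz  = sqrt(ax^2 + az^2)

An impact burst is judged by three phases in precedence order:

1. **Phase 1 — critical.** `SVM_xyz > 6 G`: harder than any daily
   activity.
2. **Phase 3 — critical.** `SVM_xz > 2 G` at some sample K (the torso
   tilts over), the body comes to rest (within 0.2 G of 1 G for 0.3 s)
   at some L within 2 s of K, and the reference velocity
   `V = ∫[K,L] (SVM_xyz(t) − 1 G) · g dt` exceeds 1.7 m/s. This catches
   falls whose peak acceleration alone looks like a daily activity.
3. **Phase 2 — normal.** `SVM_xyz > 3.5 G`: a cancellable alarm; the
   wearer can press and hold the emergency button (2 s within 30 s) to
   cancel it. Critical alarms can never be canceled.

## The positioning engine

M reference nodes at known coordinates and the wearable each observe the
broadcasts of N RF generators, giving RSSI vectors `W` and `R_i` on the
radio's 0–255 scale. Raw values are first adjusted by the class-dependent
weighting `rss' = A + ratio · (rss − B)` (four distance classes with
printed parameters at 25 °C), then the wearable is matched to reference
nodes by Euclidean distance in RSSI space:

    e_i = sqrt( Σ_j (w_j − r_ij)^2 )

The p = 4 nearest nodes are combined with normalized inverse-square
weights, `w_k ∝ 1/e_k²`, so the most similar node dominates the estimated
position `(x, y) = Σ w_k (x_k, y_k)`. Accuracy is reported as the planar
error distance to the true position.

## Worked example

```r
library(telefall)

scenario <- fall_scenario(pre_activity = "walk", direction = "front",
                          impact_peak = 6.5, seed = 42)
sim <- generate_fall_trace(scenario)
sim$trace
#> accel_trace: 560 samples @ 200 Hz (2.800 s), t0 = 0 s

events <- apply_cancellation(detect(sim$trace))
events[, c("t", "severity", "phase", "peak_svm_xyz", "status")]
#>       t severity phase peak_svm_xyz    status
#> 1 1.735 critical     1     6.490332 confirmed

layout <- grid_layout(11, 5.75, node_spacing = 2, n_generators = 5)
layout
#> node_layout: 11.00 x 5.75 m room, 18 reference nodes, 5 generators

res <- run_pipeline(sim$trace, layout, wearable_position = c(4.2, 3.1),
                    pl = path_loss_params(sigma = 2), seed = 42)
est <- res[[1]]$position
est
#> position_estimate: (5.375, 3.834) m from 4 neighbors
error_distance(est, c(4.2, 3.1))
#> [1] 1.39
```

The walking-then-falling trace raises one critical phase-1 alarm (its
6.49 G peak exceeds every daily activity), the alarm triggers one RSSI
collection round in the simulated 18-node classroom deployment, and the
weighted 4-nearest-neighbor estimate lands 1.39 m from the true position
under 2 dB of shadowing noise.

The same operations are available from a shell via `exec/telefall`
(`simulate-accel`, `simulate-rssi`, `detect`, `locate`, `run`, `eval`).

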