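---
title: "Methods: threshold fall detection and weighted-RSSI positioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold fall detection and weighted-RSSI positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telefall)
```

`telefall` models a waist-worn telecare system with two cooperating parts:
a threshold-based fall detector on a 200 Hz tri-axial accelerometer
stream, and an indoor positioning engine that a confirmed alarm triggers.
This vignette documents the models, the parameters that matter, the
numerical choices, what the simulators do and do not emulate, and the
package's known limitations.

## 1. The fall model and the three-phase detector

A fall has three mechanical stages: a brief **free fall** (acceleration
magnitude dips below 1 G), an **impact** (a sharp spike), and **lying on
the ground** (magnitude static near 1 G). The detector works on two
per-sample features of the trace: the sum vector magnitude
`SVM_xyz = sqrt(ax² + ay² + az²)` and its horizontal (x–z plane)
projection `SVM_xz = sqrt(ax² + az²)`, both in G. Features are computed on
raw samples; no low-pass filter is applied, and users who need filtering
should apply it upstream.

### Thresholds

| parameter | default | unit | meaning |
|---|---|---|---|
| `th_high_xyz` | 6.0 | G | maximum `SVM_xyz` over *all* daily activities; above it a fall is certain and critical |
| `th_low_xyz` | 3.5 | G | maximum `SVM_xyz` over *normal-speed* daily activities; above it a cancellable normal alarm is raised |
| `th_xz` | 2.0 | G | horizontal magnitude a toppling torso exceeds; opens a phase-3 candidate at sample K |
| `th_v` | 1.7 | m/s | reference-velocity bound separating critical falls from violent daily activities |
| `rest_window_s` | 0.3 | s | how long the body must stay near 1 G to count as lying still |
| `search_window_s` | 2.0 | s | horizon after K within which rest must begin |
| `rest_epsilon_g` | 0.2 | G | half-width of the rest band around 1 G |
| `refractory_s` | 2.0 | s | one alarm per physical impact |
| `cancel_hold_s` / `cancel_timeout_s` | 2 / 30 | s | button hold and acceptance window for cancelling a normal alarm |

The first four are the algorithm's operating point; the rest are
implementation parameters that the underlying flow chart leaves open, and
every one is configurable through `detector_config()`.

### Region-based precedence

The three phases are not evaluated sample-by-sample. A candidate region
opens at the first sample exceeding `th_low_xyz` or `th_xz` and spans one
`search_window_s`; the phases are then tried on the whole region in the
order **phase 1 > phase 3 > phase 2**. Judging the burst as a whole
matters: an impact crosses the lower thresholds on its rising edge a few
samples before it crosses 6 G, and a per-sample scan would label a hard
impact as a lesser alarm (or as phase 3) before ever seeing its peak.
Critical-by-peak dominates critical-by-velocity, which dominates the
normal alarm; phase 3 is evaluated independently of whether the 3.5 G
threshold was crossed, because slump-style falls with sub-3.5 G peaks are
precisely the ones only the velocity criterion can catch.

### The reference velocity

Phase 3 integrates the gravity-subtracted magnitude between the
horizontal trigger K and the rest onset L:

`V = ∫[K,L] (SVM_xyz(t) − 1) · g dt`,  `g = 9.80665 m/s²` per G
(configurable; the conversion constant is a package choice, as the
quantity is defined in G but compared against a threshold in m/s).

Numerical choices, all deliberate:

* **Trapezoidal quadrature** at the native sample spacing
  (`pracma::trapz`): second-order accurate, deterministic, and
  interval-additive, so `V[K,L] = V[K,M] + V[M,L]` holds exactly.
* **No clamping of the integrand at zero**: sub-1 G (free-fall) segments
  legitimately reduce the velocity estimate, and the signed integral is
  compared against `th_v`.
* **"Static" is defined**, since the flow chart leaves it open, as every
  sample within `rest_epsilon_g` of 1 G for a full `rest_window_s`; L is
  the first qualifying rest start after K, K the first horizontal
  crossing in the region; ties resolve to the earliest index.
* If no rest begins within `search_window_s` of K, phase 3 does not fire:
  a body that never comes to rest is not lying on the ground.
* Uniform sampling is assumed and validated (1e-6 s tolerance on the CSV
  reader); irregular input is rejected rather than resampled.

### Alarm semantics

Critical alarms (phases 1 and 3) demand immediate help and cannot be
canceled. Normal alarms (phase 2) are cancellable: a button press
starting within `cancel_timeout_s` of the trigger and held for
`cancel_hold_s` cancels them, modelling the wearer getting up after a
minor stumble. Presses are data (`press_time`, `hold_duration`), not
hardware. A refractory window of `refractory_s` after each trigger
suppresses duplicate alarms from one impact; consecutive triggers are
therefore always at least that far apart.

## 2. The radio model and the weighting transform

Received power follows the log-distance path-loss model

`P(d) = P(d0) − 10 n log10(d / d0) + X_sigma`

with exponent `n = 2` (free space) and zero-mean Gaussian shadowing
`X_sigma` in dB. The radio reports an integer RSSI on 0–255 obtained
linearly from dBm. The chip's own line is not published, so the package
fits the unique line through two class anchors — readings within 0.5 m
map to RSSI 144 and readings at 7 m map to RSSI 60 — which makes the
simulated RSSI field independent of the absolute transmit power
(`pl_d0`, default −40 dBm at 1 m, cancels out of the calibrated map) and
reproduces the distance semantics of the four RSSI classes:

| class | RSSI range | distance | A | ratio | B |
|---|---|---|---|---|---|
| I | 144–255 | < 0.5 m | 176 | 0.05 | 144 |
| II | 112–143 | 0.5–2 m | 112 | 0.3 | 112 |
| III | 61–111 | 2–7 m | 60 | 0.6 | 60 |
| IV | 0–60 | > 7 m | 0 | 1 | 0 |

The printed class ranges meet at 60; the package assigns 60 to Class IV
so the classes partition 0–255 — the choice is observationally neutral
because both parameterizations give the identical weighted value 60
there. Before distances are computed, every raw value is adjusted by the
class's linear transform `rss' = A + ratio (rss − B)` (the **weighted
RSSI**), strictly increasing over the whole scale, which compresses the
volatile near-field classes. Tables for other conditions (temperature,
humidity) can be supplied as plain data frames or JSON; only the 25 °C
table ships with the package.

## 3. The positioning engine

One collection round gives the wearable's RSSI vector `W` over the N
generators and each reference node's vector `R_i`. Matching happens in
RSSI space: `e_i = ||W' − R_i'||` (weighted values on both sides, or raw
values when `use_weighting = FALSE`). The p nearest reference nodes are
combined as a convex combination of their known coordinates with
normalized inverse-square weights `w_k = (1/e_k²) / Σ (1/e_i²)` — the
node most similar in radio view contributes most, the standard weighting
of reference-tag kNN localization schemes (and pluggable, since the exact
algebraic form is a design choice). Two degenerate rules keep the
estimator total and deterministic: nodes at exactly zero RSSI distance
absorb the whole weight mass (split equally; the limit of inverse-square
weighting), and ties at the p-th distance break by ascending node id.
`p = 4` by default, the error-minimizing choice in the reference
deployment. Estimates are therefore always inside the bounding box of the
selected neighbors, and translating the whole layout translates the
estimate identically.

## 4. What the simulators emulate — and what they do not

### Accelerometer traces

`generate_fall_trace()` composes a pre-activity segment (one of the eight
activities-before-falling, e.g. walking or standing up), an optional
linear free-fall dip below 1 G, a half-sine impact spike reaching
`impact_peak` whose direction splits the magnitude between the vertical
axis and the direction-appropriate horizontal axis
(`horizontal_fraction`, default 0.65), an optional sustained post-impact
excess (slump/slide), and a rest segment near 1 G, plus Gaussian jitter
(sd 0.02 G) on every axis. Only the 28 realistic
(pre-activity, direction) combinations are accepted — six activities in
all four fall directions, walking backward in three, and rolling off the
bed as a single left-lateral scenario. `generate_adl_trace()` produces
the seven daily activities at normal or fast speed (running:
normal only) with fixed per-activity peak magnitudes chosen so that
normal-speed house activities stay below 3.5 G while a fast jump exceeds
6 G and fast stair use and fast lying-down exceed 3.5 G — deliberate
false alarms that mirror how acute activities overlap genuine fall
accelerations. Every generator is deterministic given its seed and emits
ground-truth labels, so detector evaluation is fully self-contained.

The morphology is parametric and simple by design. It does **not**
emulate subject-to-subject variability, sensor mounting slack,
orientation drift, or the measured acceleration distributions of real
falls; a detector that passes these tests is verified as an algorithm,
not validated on human data.

### Radio rounds

`simulate_round()` plays one collection round synchronously in process:
each generator broadcasts in turn, every observer (wearable plus all
reference nodes) reports one integer RSSI per generator through the
calibrated map, with seeded shadowing noise. Distances are floored at
1 cm to keep co-located nodes inside the model's domain. The default
deployment (`grid_layout()`) reconstructs an 11 × 5.75 m room with 18
reference nodes on a centered 2 m grid (6 × 3), the gateway at the room
center and 5 generators placed symmetrically about it at quarter-room
offsets; exact node coordinates of the physical deployment are not
published, so any arrangement can be supplied instead. Packet loss,
multipath, antenna patterns and environmental drift are not modelled.

### A known, deliberate limitation

The simulated RSSI field is *exactly* log-linear in log-distance. The
class weighting, however, exists to correct the **non**-log-linear
behavior of real radios (saturation below 0.5 m, rapid decay beyond
7 m). On a perfectly log-linear field the transform has nothing to
correct, and measurably *increases* the mean positioning error relative
to raw RSSI (by roughly 0.1–0.2 m at 2 dB shadowing in the reference
deployment) because it rescales the steep, informative near-field
coordinates down relative to the shallow far-field ones. The package
keeps the faithful log-distance generator and reports the weighted-vs-raw
comparison honestly; reproducing the real-radio benefit of the weighting
would require a generator with the surveyed non-linearity, which no
published parameters support.

## 5. Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data
at desk scale, the package's own choice of benchmark: feature checks on
1,000 short random traces; an exhaustive sweep of all 256 RSSI values;
100 random localization instances (M ≤ 18, N ≤ 5, p ≤ 6) against a naive
brute-force oracle; detector fixtures for each phase with closed-form
reference velocities; 200 Monte-Carlo positioning trials per shadowing
level at σ ∈ {0, 1, 2, 4} dB; and a detection benchmark of 56 fall plus
65 daily-activity traces. Mean positioning error grows monotonically with
σ, and zero-noise rounds recover every reference-node position exactly.
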