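# Synthetic-data generation: accelerometer traces for falls and activities
# of daily living (ADLs), grid deployments, and RSSI collection rounds.
# Trace morphology (half-sine impact spike, linear free-fall ramp, small
# Gaussian jitter) is a deliberately simple parametric emulation of the
# free-fall / impact / lying-on-ground stages of a real fall.

fall_pre_activities <- c("stand", "sit-to-stand", "stand-to-sit", "walk",
                         "stoop", "jump", "walk-backward", "lie-then-turn")
fall_directions <- c("front", "posterior", "left-lateral", "right-lateral")

# The 28 valid (pre_activity, direction) pairs: six activities in all four
# directions, walking backward in three (no forward fall), and rolling off
# the bed as a single left-lateral scenario (sensor worn on the left waist).
valid_fall_pairs <- function() {
  base <- expand.grid(
    pre_activity = setdiff(fall_pre_activities, c("walk-backward", "lie-then-turn")),
    direction = fall_directions, stringsAsFactors = FALSE)
  rbind(base,
        data.frame(pre_activity = "walk-backward",
                   direction = c("posterior", "left-lateral", "right-lateral")),
        data.frame(pre_activity = "lie-then-turn", direction = "left-lateral"))
}

adl_activities <- c("stand-up", "sit-down", "lie-on-bed", "walk", "jump",
                    "stairs", "run")

# Peak sum-vector magnitudes (G) per activity and speed. Normal-speed house
# activities stay under the 3.5 G normal-alarm threshold; fast lying-down
# and fast stair use cross it (designed cancellable false alarms) and a
# fast jump crosses the 6 G critical threshold (designed critical false
# alarm), mirroring how acute activities overlap real fall accelerations.
adl_peaks <- list(
  "stand-up"   = c(normal = 1.8, fast = 2.8),
  "sit-down"   = c(normal = 2.0, fast = 3.2),
  "lie-on-bed" = c(normal = 1.6, fast = 3.8),
  "walk"       = c(normal = 1.6, fast = 2.6),
  "jump"       = c(normal = 3.0, fast = 6.5),
  "stairs"     = c(normal = 2.2, fast = 4.2),
  "run"        = c(normal = 2.8, fast = NA))

#' Fall scenario
#'
#' Parameters of one synthetic fall: the activity performed before the
#' fall, the fall direction, and the shape of the three fall stages
#' (optional free-fall dip below 1 G, impact spike, post-impact rest).
#' Only the 28 realistic (pre_activity, direction) pairs are accepted.
#'
#' @param pre_activity One of `r paste(fall_pre_activities, collapse=", ")`.
#' @param direction One of front, posterior, left-lateral, right-lateral.
#' @param impact_peak Peak sum-vector magnitude of the impact in G (> 1).
#' @param free_fall_depth Depth of the pre-impact dip below 1 G (>= 0; 0
#'   disables the dip).
#' @param free_fall_duration Dip duration in seconds.
#' @param impact_duration Duration of the half-sine impact spike in seconds.
#' @param horizontal_fraction Fraction of the impact magnitude lying in the
#'   horizontal (x-z) plane, or NULL for the per-direction default (0.65).
#'   Controls whether the trace can open a phase-3 candidate.
#' @param post_impact_excess_g Sustained excess over 1 G after the impact
#'   (slump/slide before coming to rest); 0 disables the segment.
#' @param post_impact_duration_s Duration of the sustained excess, seconds.
#' @param rest_duration Post-impact rest duration in seconds (>= 0.3 for a
#'   ground-truth fall: the body must lie still).
#' @param seed Integer seed making the jitter reproducible.
#' @return An object of class `fall_scenario`.
#' @export
fall_scenario <- function(pre_activity = "stand", direction = "front",
                          impact_peak = 6.5, free_fall_depth = 0.4,
                          free_fall_duration = 0.2, impact_duration = 0.1,
                          horizontal_fraction = NULL,
                          post_impact_excess_g = 0,
                          post_impact_duration_s = 0,
                          rest_duration = 1.0, seed = 1L) {
  pairs <- valid_fall_pairs()
  if (!any(pairs$pre_activity == pre_activity & pairs$direction == direction))
    stopf("scenario error: (%s, %s) is not one of the %d valid fall scenarios",
          pre_activity, direction, nrow(pairs))
  if (impact_peak <= 1) stopf("impact_peak must exceed 1 G")
  if (free_fall_depth < 0 || free_fall_depth > 1)
    stopf("free_fall_depth must be in [0, 1] G")
  if (rest_duration < 0.3)
    stopf("rest_duration must be >= 0.3 s for a ground-truth fall")
  if (!is.null(horizontal_fraction) &&
      (horizontal_fraction < 0 || horizontal_fraction >= 1))
    stopf("horizontal_fraction must be in [0, 1)")
  structure(list(pre_activity = pre_activity, direction = direction,
                 impact_peak = impact_peak,
                 free_fall_depth = free_fall_depth,
                 free_fall_duration = free_fall_duration,
                 impact_duration = impact_duration,
                 horizontal_fraction = horizontal_fraction,
                 post_impact_excess_g = post_impact_excess_g,
                 post_impact_duration_s = post_impact_duration_s,
                 rest_duration = rest_duration, seed = as.integer(seed)),
            class = "fall_scenario")
}

#' ADL scenario
#'
#' One activity of daily living at normal or fast speed; running is
#' normal-speed only. Ground truth for these traces is always "no fall".
#'
#' @param activity One of `r paste(adl_activities, collapse=", ")`.
#' @param speed "normal" or "fast".
#' @param duration Trace duration in seconds.
#' @param seed Integer seed.
#' @return An object of class `adl_scenario`.
#' @export
adl_scenario <- function(activity = "walk", speed = "normal", duration = 4,
                         seed = 1L) {
  if (!activity %in% adl_activities)
    stopf("scenario error: unknown activity '%s'", activity)
  if (!speed %in% c("normal", "fast"))
    stopf("scenario error: speed must be 'normal' or 'fast'")
  if (activity == "run" && speed == "fast")
    stopf("scenario error: running is modelled at normal speed only")
  if (duration <= 0) stopf("duration must be > 0")
  structure(list(activity = activity, speed = speed, duration = duration,
                 seed = as.integer(seed)),
            class = "adl_scenario")
}

# Unit impact direction: horizontal_fraction hf of the magnitude lies along
# the direction's horizontal axis, the rest is vertical (y).
impact_unit <- function(direction, hf) {
  h <- switch(direction,
              "front"         = c(0, 0, 1),
              "posterior"     = c(0, 0, -1),
              "right-lateral" = c(1, 0, 0),
              "left-lateral"  = c(-1, 0, 0))
  c(h[1] * hf, sqrt(1 - hf^2), h[3] * hf)
}

# Build an axis matrix (n x 3) from an svm magnitude profile along a unit
# direction u, so that the sum vector magnitude equals the profile exactly
# (before jitter).
profile_to_axes <- function(mag, u = c(0, 1, 0)) {
  cbind(mag * u[1], mag * u[2], mag * u[3])
}

pre_activity_profile <- function(activity, sr, duration = 1.5) {
  n <- max(2L, round(duration * sr))
  t <- (seq_len(n) - 1) / sr
  mag <- switch(activity,
    "walk" = , "walk-backward" = 1 + 0.4 * abs(sin(2 * pi * 1.8 * t)),
    "jump" = 1 + 1.5 * exp(-((t - duration / 2)^2) / (2 * 0.05^2)),
    "sit-to-stand" = , "stand-to-sit" =
      1 + 0.6 * sin(pi * clamp(t / duration, 0, 1)),
    "stoop" = 1 + 0.5 * sin(pi * clamp(t / duration, 0, 1)),
    # stand, lie-then-turn: quiet posture
    rep(1, n))
  mag
}

#' Generate a synthetic fall trace with ground truth
#'
#' Assembles pre-activity, optional free-fall dip, half-sine impact spike
#' (reaching `impact_peak`, oriented by `direction`), optional sustained
#' post-impact excess, and a rest segment near 1 G, plus small Gaussian
#' jitter (sd 0.02 G) on every axis. Deterministic given the scenario seed.
#'
#' @param scenario A [fall_scenario()].
#' @param sample_rate_hz Sampling rate in Hz (default 200).
#' @return A list of class `labeled_trace`: `trace` (an [accel_trace()]),
#'   `label` ("fall"), `fall_start`/`fall_end` (sample indices of the fall
#'   interval), and `expected_severity` ("critical", "normal" or "none",
#'   the generator's intent given the scenario parameters).
#' @export
generate_fall_trace <- function(scenario, sample_rate_hz = 200) {
  stopifnot(inherits(scenario, "fall_scenario"))
  sr <- sample_rate_hz
  hf <- scenario$horizontal_fraction %||% 0.65
  u <- impact_unit(scenario$direction, hf)

  pre <- profile_to_axes(pre_activity_profile(scenario$pre_activity, sr))
  fall_segments <- list()
  if (scenario$free_fall_depth > 0 && scenario$free_fall_duration > 0) {
    nf <- max(2L, round(scenario$free_fall_duration * sr))
    half <- ceiling(nf / 2)
    dip <- 1 - scenario$free_fall_depth *
      c(seq(0, 1, length.out = half), seq(1, 0, length.out = nf - half + 1))[-half]
    fall_segments$dip <- profile_to_axes(dip)
  }
  ni <- max(2L, round(scenario$impact_duration * sr))
  spike <- 1 + (scenario$impact_peak - 1) * sin(pi * (seq_len(ni) - 1) / (ni - 1))
  fall_segments$impact <- profile_to_axes(spike, u)
  if (scenario$post_impact_excess_g > 0 && scenario$post_impact_duration_s > 0) {
    np <- max(2L, round(scenario$post_impact_duration_s * sr))
    fall_segments$post <- profile_to_axes(
      rep(1 + scenario$post_impact_excess_g, np), u)
  }
  nr <- max(2L, round(scenario$rest_duration * sr))
  rest <- profile_to_axes(rep(1, nr))

  fall_mat <- do.call(rbind, fall_segments)
  mat <- rbind(pre, fall_mat, rest)
  mat <- mat + with_seed(scenario$seed,
                         matrix(stats::rnorm(length(mat), 0, 0.02), nrow(mat)))

  expected <- if (scenario$impact_peak > 6) {
    "critical"
  } else if (hf * scenario$impact_peak <= 2 || scenario$rest_duration < 0.3) {
    if (scenario$impact_peak > 3.5) "normal" else "none"
  } else {
    # closed-form reference velocity intent: the integration starts at K,
    # where the horizontal magnitude first crosses 2 G, so only the tail
    # of the half-sine impact area counts, plus any sustained excess
    theta <- asin(clamp((2 / hf - 1) / (scenario$impact_peak - 1), 0, 1))
    frac <- (1 + cos(theta)) / 2
    v <- 9.80665 *
      (frac * (2 / pi) * (scenario$impact_peak - 1) * scenario$impact_duration +
       scenario$post_impact_excess_g * scenario$post_impact_duration_s)
    if (v > 1.7) "critical"
    else if (scenario$impact_peak > 3.5) "normal"
    else "none"
  }
  structure(list(
    trace = accel_trace(mat[, 1], mat[, 2], mat[, 3], sample_rate_hz = sr),
    label = "fall",
    fall_start = nrow(pre) + 1L,
    fall_end = nrow(pre) + nrow(fall_mat),
    expected_severity = expected),
    class = "labeled_trace")
}

#' Generate a synthetic ADL trace with ground truth
#'
#' Single smooth bumps for posture changes (stand up, sit down, lie down),
#' periodic oscillations for gait activities (walk, run, stairs), and a
#' dip-spike-landing pattern for jumps. Peak magnitudes follow a fixed
#' per-activity table (see the package vignette); the impact direction is
#' kept mostly vertical so ADLs do not open horizontal-plane fall
#' candidates. Deterministic given the scenario seed.
#'
#' @param scenario An [adl_scenario()].
#' @param sample_rate_hz Sampling rate in Hz (default 200).
#' @return A `labeled_trace` list with `label` "adl" and
#'   `expected_severity` "none".
#' @export
generate_adl_trace <- function(scenario, sample_rate_hz = 200) {
  stopifnot(inherits(scenario, "adl_scenario"))
  sr <- sample_rate_hz
  n <- max(4L, round(scenario$duration * sr))
  t <- (seq_len(n) - 1) / sr
  peak <- adl_peaks[[scenario$activity]][[scenario$speed]]
  u <- c(0.15, sqrt(1 - 2 * 0.15^2), 0.15)  # mostly vertical loading

  mag <- switch(scenario$activity,
    "stand-up" = , "sit-down" = , "lie-on-bed" = {
      # quiet - smooth bump in the middle third - quiet
      b0 <- floor(n / 3); b1 <- min(n, b0 + round(0.5 * sr))
      m <- rep(1, n)
      m[b0:b1] <- 1 + (peak - 1) * sin(pi * (0:(b1 - b0)) / (b1 - b0))
      m
    },
    "walk" = , "run" = , "stairs" = {
      f <- if (scenario$speed == "fast") 2.4 else 1.8
      1 + (peak - 1) * 0.5 * (1 - cos(2 * pi * f * t))
    },
    "jump" = {
      m <- rep(1, n)
      b0 <- max(1L, floor(n / 3))
      nd <- round(0.2 * sr)                       # takeoff unloading
      i1 <- clamp(b0:(b0 + nd), 1L, n)
      m[i1] <- 1 - 0.4 * sin(pi * (seq_along(i1) - 1) / nd)
      ns <- max(2L, round(0.08 * sr))             # landing spike
      s0 <- b0 + nd + 1L
      i2 <- clamp(s0:(s0 + ns), 1L, n)
      m[i2] <- 1 + (peak - 1) * sin(pi * (seq_along(i2) - 1) / ns)
      m
    })
  mat <- profile_to_axes(mag, u)
  mat <- mat + with_seed(scenario$seed,
                         matrix(stats::rnorm(length(mat), 0, 0.02), nrow(mat)))
  structure(list(
    trace = accel_trace(mat[, 1], mat[, 2], mat[, 3], sample_rate_hz = sr),
    label = "adl", fall_start = NA_integer_, fall_end = NA_integer_,
    expected_severity = "none"),
    class = "labeled_trace")
}

#' Regular grid deployment layout
#'
#' Places reference nodes on a regular grid at the given spacing, centered
#' in the room, the gateway at the room center, and the RF generators
#' symmetrically about the center (first at the center, then in symmetric
#' pairs at quarter-room offsets). The default geometry (11 x 5.75 m room,
#' 2 m spacing, 5 generators) yields 18 reference nodes in a 6 x 3 grid.
#'
#' @param room_length,room_width Room dimensions in meters.
#' @param node_spacing Grid spacing in meters; must not exceed either room
#'   dimension.
#' @param n_generators Number of RF generators (1-9).
#' @return A [node_layout()].
#' @export
grid_layout <- function(room_length = 11, room_width = 5.75,
                        node_spacing = 2, n_generators = 5) {
  if (node_spacing <= 0) stopf("node_spacing must be > 0")
  if (node_spacing > room_length || node_spacing > room_width)
    stopf("layout error: node_spacing exceeds a room dimension")
  nx <- floor(room_length / node_spacing) + 1
  ny <- floor(room_width / node_spacing) + 1
  xs <- (room_length - (nx - 1) * node_spacing) / 2 +
    (seq_len(nx) - 1) * node_spacing
  ys <- (room_width - (ny - 1) * node_spacing) / 2 +
    (seq_len(ny) - 1) * node_spacing
  grid <- expand.grid(x = xs, y = ys)
  nodes <- data.frame(id = sprintf("R%02d", seq_len(nrow(grid))),
                      x = grid$x, y = grid$y, stringsAsFactors = FALSE)
  cx <- room_length / 2; cy <- room_width / 2
  offs <- rbind(c(0, 0),
                c(-1, -1), c(1, 1), c(-1, 1), c(1, -1),
                c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (n_generators < 1 || n_generators > nrow(offs))
    stopf("n_generators must be between 1 and %d", nrow(offs))
  gp <- offs[seq_len(n_generators), , drop = FALSE]
  gens <- data.frame(id = sprintf("G%d", seq_len(n_generators)),
                     x = cx + gp[, 1] * room_length / 4,
                     y = cy + gp[, 2] * room_width / 4,
                     stringsAsFactors = FALSE)
  node_layout(room_length, room_width, nodes, gens, c(cx, cy))
}

#' Simulate one RSSI collection round
#'
#' Emulates the collection protocol in process: each RF generator
#' broadcasts in turn and every observer (the wearable plus every reference
#' node) reports one RSSI value per generator. Received powers come from
#' the log-distance path-loss model with optional Gaussian shadowing and
#' are mapped to the 0-255 scale with the class-anchor calibration
#' ([calibrate_rssi_map()]). Deterministic given the seed.
#'
#' @param layout A [node_layout()].
#' @param wearable_position Numeric `c(x, y)` inside the room.
#' @param pl A [path_loss_params()]; `pl$sigma` > 0 adds shadowing noise.
#' @param seed Integer seed for the shadowing draws.
#' @param min_distance Observer-generator distances are floored at this
#'   value (meters) so co-located nodes stay within the model's domain.
#' @return An [rssi_round()].
#' @export
simulate_round <- function(layout, wearable_position,
                           pl = path_loss_params(), seed = 1L,
                           min_distance = 0.01) {
  stopifnot(inherits(layout, "node_layout"))
  wp <- as.numeric(wearable_position)
  if (length(wp) != 2 || any(wp < 0) || wp[1] > layout$room["length"] ||
      wp[2] > layout$room["width"])
    stopf("geometry error: wearable position must lie inside the room")
  obs <- rbind(wp, as.matrix(layout$reference_nodes[, c("x", "y")]))
  gens <- as.matrix(layout$rf_generators[, c("x", "y")])
  d <- sqrt(outer(obs[, 1], gens[, 1], "-")^2 +
            outer(obs[, 2], gens[, 2], "-")^2)
  d <- pmax(d, min_distance)
  noise <- if (pl$sigma > 0) {
    with_seed(seed, matrix(stats::rnorm(length(d), 0, pl$sigma), nrow(d)))
  } else 0
  cal <- calibrate_rssi_map(pl)
  p <- path_loss_power(d, pl) + noise
  r <- matrix(dbm_to_rssi(p, cal$slope, cal$intercept), nrow(d))
  refs <- r[-1, , drop = FALSE]
  dimnames(refs) <- list(layout$reference_nodes$id, layout$rf_generators$id)
  rssi_round(stats::setNames(r[1, ], layout$rf_generators$id), refs)
}
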