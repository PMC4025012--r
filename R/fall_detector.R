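#' Fall detector configuration
#'
#' Thresholds and windows of the three-phase threshold detector. The
#' defaults are the operating point of the waist-worn system this package
#' models: `th_high_xyz` (6 G) is the maximum sum-vector magnitude observed
#' over all daily activities, `th_low_xyz` (3.5 G) the maximum over
#' normal-speed daily activities, `th_xz` (2 G) the horizontal-plane
#' magnitude a falling torso exceeds, and `th_v` (1.7 m/s) the reference
#' velocity separating critical falls from violent daily activities.
#'
#' @param th_high_xyz Critical peak threshold in G.
#' @param th_low_xyz Normal (cancellable) peak threshold in G; must be below
#'   `th_high_xyz`.
#' @param th_xz Horizontal-plane threshold in G that opens a phase-3
#'   candidate at sample K.
#' @param th_v Reference-velocity threshold in m/s.
#' @param rest_window_s Duration in seconds a body must stay near 1 G to
#'   count as static (lying on the ground) after the impact.
#' @param search_window_s How long after K a rest segment may begin for
#'   phase 3 to fire, in seconds.
#' @param rest_epsilon_g Half-width of the rest band around 1 G, in G.
#' @param refractory_s Minimum spacing between alarms from one physical
#'   impact, in seconds.
#' @param cancel_hold_s Minimum button hold duration that cancels a normal
#'   alarm, in seconds.
#' @param cancel_timeout_s How long after the trigger a cancel press is
#'   accepted, in seconds.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(th_high_xyz = 6.0, th_low_xyz = 3.5,
                            th_xz = 2.0, th_v = 1.7,
                            rest_window_s = 0.3, search_window_s = 2.0,
                            rest_epsilon_g = 0.2, refractory_s = 2.0,
                            cancel_hold_s = 2.0, cancel_timeout_s = 30.0) {
  cfg <- list(th_high_xyz = th_high_xyz, th_low_xyz = th_low_xyz,
              th_xz = th_xz, th_v = th_v,
              rest_window_s = rest_window_s,
              search_window_s = search_window_s,
              rest_epsilon_g = rest_epsilon_g, refractory_s = refractory_s,
              cancel_hold_s = cancel_hold_s,
              cancel_timeout_s = cancel_timeout_s)
  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) stopf("config fields must be single finite numbers: %s",
                       paste(names(cfg)[!num], collapse = ", "))
  if (any(unlist(cfg[c("th_high_xyz", "th_low_xyz", "th_xz", "th_v")]) <= 0))
    stopf("all thresholds must be > 0")
  if (cfg$th_low_xyz >= cfg$th_high_xyz)
    stopf("th_low_xyz (%g) must be below th_high_xyz (%g)",
          cfg$th_low_xyz, cfg$th_high_xyz)
  if (cfg$rest_window_s >= cfg$search_window_s)
    stopf("rest_window_s must be smaller than search_window_s")
  if (cfg$rest_epsilon_g <= 0 || cfg$refractory_s < 0 ||
      cfg$cancel_hold_s < 0 || cfg$cancel_timeout_s < 0)
    stopf("rest_epsilon_g must be > 0 and durations must be >= 0")
  structure(cfg, class = "detector_config")
}

#' Read a detector configuration from YAML or JSON
#'
#' The file holds a mapping whose keys mirror the [detector_config()]
#' arguments; absent keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `detector_config`.
#' @export
read_detector_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(detector_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0)
    stopf("unknown detector config keys: %s", paste(extra, collapse = ", "))
  do.call(detector_config, vals)
}

empty_events <- function() {
  data.frame(severity = character(), phase = integer(),
             trigger_index = integer(), k_index = integer(),
             l_index = integer(), peak_svm_xyz = numeric(),
             v_max = numeric(), t = numeric(), status = character(),
             stringsAsFactors = FALSE)
}

#' Detect falls in an accelerometer trace
#'
#' Runs the three-phase threshold algorithm over the feature series and
#' returns the detected alarms in trigger order. A candidate region opens
#' at the first sample whose sum vector magnitude exceeds `th_low_xyz` or
#' whose horizontal magnitude exceeds `th_xz`, and spans one
#' `search_window_s` -- the same horizon within which a fallen body must
#' come to rest. The phases are then tried on the region in precedence
#' order (an impact burst is judged as a whole, so a hard impact is never
#' mistaken for a lesser alarm on its rising edge):
#'
#' * Phase 1 (critical): some sample in the region exceeds `th_high_xyz` --
#'   the impact is harder than any daily activity. Trigger = that sample.
#' * Phase 3 (critical): the horizontal magnitude exceeds `th_xz` at some
#'   sample K, a rest segment (every sample within `rest_epsilon_g` of 1 G
#'   for a full `rest_window_s`) begins at some L within `search_window_s`
#'   after K, and the reference velocity over \[K, L\] exceeds `th_v`.
#'   Trigger = K.
#' * Phase 2 (normal, cancellable): some sample in the region exceeds
#'   `th_low_xyz`. Trigger = the first such sample.
#'
#' After an alarm the scan skips a refractory window so one physical impact
#' raises one alarm. If the trace ends before a search window does, the
#' search is truncated at end-of-trace.
#'
#' @param trace An [accel_trace()].
#' @param config A [detector_config()].
#' @return A data.frame of events (class `fall_events`) with columns
#'   `severity` ("critical"/"normal"), `phase` (1, 2 or 3), `trigger_index`,
#'   `k_index`/`l_index` (phase 3 only, else NA), `peak_svm_xyz` (G, maximum
#'   over the refractory window after the trigger), `v_max` (m/s, phase 3
#'   only), `t` (trigger time in seconds) and `status` ("raised").
#' @export
detect <- function(trace, config = detector_config()) {
  stopifnot(inherits(trace, "accel_trace"), inherits(config, "detector_config"))
  f <- compute_features(trace)
  n <- nrow(f)
  sr <- trace$sample_rate_hz
  rest_w <- max(1L, as.integer(round(config$rest_window_s * sr)))
  search_w <- max(1L, as.integer(round(config$search_window_s * sr)))
  refr_w <- max(1L, as.integer(round(config$refractory_s * sr)))

  # rest_start[j]: the rest_w samples beginning at j all lie in the rest band
  is_rest <- abs(f$svm_xyz - 1) <= config$rest_epsilon_g
  rest_start <- rep(FALSE, n)
  if (n >= rest_w) {
    cs <- cumsum(is_rest)
    wsum <- cs[rest_w:n] - c(0, cs[seq_len(n - rest_w)])
    rest_start[seq_len(n - rest_w + 1L)] <- wsum == rest_w
  }

  events <- list()
  i <- 1L
  while (i <= n) {
    if (f$svm_xyz[i] <= config$th_low_xyz && f$svm_xz[i] <= config$th_xz) {
      i <- i + 1L
      next
    }
    win <- i:min(n, i + search_w)
    ev <- NULL
    hi <- win[f$svm_xyz[win] > config$th_high_xyz]
    if (length(hi) > 0) {
      ev <- list(severity = "critical", phase = 1L, trigger_index = hi[1],
                 k_index = NA_integer_, l_index = NA_integer_,
                 v_max = NA_real_)
    } else {
      ks <- win[f$svm_xz[win] > config$th_xz]
      if (length(ks) > 0) {
        k <- ks[1]
        jmax <- min(n, k + search_w)
        js <- if (k + 1L <= jmax) (k + 1L):jmax else integer(0)
        js <- js[rest_start[js]]
        if (length(js) > 0) {
          l <- js[1]
          v <- reference_velocity(trace, k, l)
          if (v > config$th_v) {
            ev <- list(severity = "critical", phase = 3L, trigger_index = k,
                       k_index = k, l_index = l, v_max = v)
          }
        }
      }
      if (is.null(ev)) {
        lo <- win[f$svm_xyz[win] > config$th_low_xyz]
        if (length(lo) > 0) {
          ev <- list(severity = "normal", phase = 2L, trigger_index = lo[1],
                     k_index = NA_integer_, l_index = NA_integer_,
                     v_max = NA_real_)
        }
      }
    }
    if (!is.null(ev)) {
      trig <- ev$trigger_index
      pw <- trig:min(n, trig + refr_w)
      ev$peak_svm_xyz <- max(f$svm_xyz[pw])
      ev$t <- trace$t0 + (trig - 1) / sr
      ev$status <- "raised"
      events[[length(events) + 1L]] <- ev
      i <- trig + refr_w
    } else {
      i <- i + 1L
    }
  }

  out <- if (length(events) == 0) empty_events() else
    do.call(rbind, lapply(events, function(e)
      data.frame(severity = e$severity, phase = e$phase,
                 trigger_index = e$trigger_index, k_index = e$k_index,
                 l_index = e$l_index, peak_svm_xyz = e$peak_svm_xyz,
                 v_max = e$v_max, t = e$t, status = e$status,
                 stringsAsFactors = FALSE)))
  class(out) <- c("fall_events", "data.frame")
  out
}

#' Apply emergency-button cancellations to detected events
#'
#' A normal (phase-2) alarm is canceled when the wearer presses and holds
#' the emergency button: the press must start within `cancel_timeout_s` of
#' the trigger and be held at least `cancel_hold_s`. Critical alarms can
#' never be canceled. Every event that is not canceled becomes confirmed.
#'
#' @param events A `fall_events` data.frame from [detect()].
#' @param button_presses A data.frame with columns `press_time` (seconds,
#'   same clock as the trace) and `hold_duration` (seconds, >= 0), sorted by
#'   time; or NULL for no presses.
#' @param config The [detector_config()] supplying the hold/timeout windows.
#' @return The events with `status` set to "canceled" or "confirmed".
#' @export
apply_cancellation <- function(events, button_presses = NULL,
                               config = detector_config()) {
  stopifnot(inherits(events, "fall_events"), inherits(config, "detector_config"))
  if (is.null(button_presses))
    button_presses <- data.frame(press_time = numeric(),
                                 hold_duration = numeric())
  if (!all(c("press_time", "hold_duration") %in% names(button_presses)))
    stopf("button_presses needs columns press_time, hold_duration")
  if (any(button_presses$hold_duration < 0))
    stopf("invalid input: negative hold duration")
  if (nrow(events) == 0) return(events)
  held <- button_presses[button_presses$hold_duration >= config$cancel_hold_s, ,
                         drop = FALSE]
  events$status <- vapply(seq_len(nrow(events)), function(i) {
    if (events$severity[i] == "normal" && nrow(held) > 0) {
      t <- events$t[i]
      if (any(held$press_time >= t &
              held$press_time <= t + config$cancel_timeout_s))
        return("canceled")
    }
    "confirmed"
  }, character(1))
  events
}

#' Write events as JSON lines
#'
#' One JSON object per line: `{"t", "severity", "phase", "peak_svm_xyz",
#' "v_max", "status"}`, with `v_max` null for phases 1 and 2.
#'
#' @param events A `fall_events` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  stopifnot(inherits(events, "fall_events"))
  lines <- vapply(seq_len(nrow(events)), function(i) {
    rec <- list(t = events$t[i], severity = events$severity[i],
                phase = events$phase[i],
                peak_svm_xyz = events$peak_svm_xyz[i],
                v_max = if (is.na(events$v_max[i])) NULL else events$v_max[i],
                status = events$status[i])
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
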