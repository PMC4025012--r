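#' Construct a tri-axial accelerometer trace
#'
#' An `accel_trace` holds a uniformly sampled tri-axial acceleration series
#' in units of G. For a waist-worn sensor the x axis is sagittal, the y axis
#' vertical, and the z axis frontal, so at quiet standing the signal is
#' approximately (0, 1, 0).
#'
#' @param ax,ay,az Numeric vectors of equal length (>= 1), acceleration in G.
#' @param sample_rate_hz Sampling rate in Hz (default 200, the rate of the
#'   waist-worn sensor this package models).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `accel_trace` with fields `ax`, `ay`, `az`,
#'   `sample_rate_hz`, `t0`.
#' @examples
#' tr <- accel_trace(ax = c(0, 0), ay = c(1, 1), az = c(0, 0))
#' trace_times(tr)
#' @export
accel_trace <- function(ax, ay, az, sample_rate_hz = 200, t0 = 0) {
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (n < 1L) stopf("empty trace: axis series must have length >= 1")
  if (length(ay) != n || length(az) != n)
    stopf("axis series must have identical length (got %d, %d, %d)",
          n, length(ay), length(az))
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stopf("invalid sample: non-finite acceleration value in trace")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stopf("sample_rate_hz must be a single positive number")
  structure(
    list(ax = ax, ay = ay, az = az,
         sample_rate_hz = as.numeric(sample_rate_hz), t0 = as.numeric(t0)),
    class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  n <- length(x$ax)
  cat(sprintf("accel_trace: %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              n, x$sample_rate_hz, n / x$sample_rate_hz, x$t0))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$ax)

#' Sample times of a trace
#'
#' @param trace An [accel_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  trace$t0 + (seq_along(trace$ax) - 1) / trace$sample_rate_hz
}

#' Sum vector magnitude of tri-axial acceleration
#'
#' The Euclidean norm sqrt(ax^2 + ay^2 + az^2), the impact feature used by
#' the fall detector. Vectorized over samples.
#'
#' @param ax,ay,az Accelerations in G (finite).
#' @return Non-negative magnitudes in G.
#' @examples
#' svm_xyz(1, 2, 2) # 3
#' @export
svm_xyz <- function(ax, ay, az) {
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stopf("invalid sample: non-finite input to svm_xyz")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Horizontal-plane sum vector magnitude
#'
#' The norm of the acceleration projected on the horizontal (x-z) plane,
#' sqrt(ax^2 + az^2); large values indicate the torso tilting forward,
#' backward or laterally. Vectorized over samples.
#'
#' @param ax,az Accelerations in G (finite).
#' @return Non-negative magnitudes in G.
#' @export
svm_xz <- function(ax, az) {
  if (!all(is.finite(ax)) || !all(is.finite(az)))
    stopf("invalid sample: non-finite input to svm_xz")
  sqrt(ax^2 + az^2)
}

#' Per-sample feature series of a trace
#'
#' Applies [svm_xyz()] and [svm_xz()] to every sample.
#'
#' @param trace An [accel_trace()].
#' @return A data.frame with columns `svm_xyz` and `svm_xz`, one row per
#'   sample, aligned 1:1 with the trace.
#' @export
compute_features <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  if (length(trace$ax) == 0L) stopf("empty trace")
  data.frame(svm_xyz = svm_xyz(trace$ax, trace$ay, trace$az),
             svm_xz  = svm_xz(trace$ax, trace$az))
}

#' Reference velocity over a sample window
#'
#' Integrates the gravity-subtracted sum vector magnitude,
#' (svm_xyz(t) - 1 G) * g, over the window `[k_index, l_index]` with the
#' trapezoidal rule at the native sample spacing. In the fall detector the
#' window runs from the horizontal-impact trigger K to the onset of
#' post-fall rest L, and the result discriminates violent (critical) falls
#' from gentler events. The integrand is deliberately not clamped at zero:
#' free-fall segments below 1 G legitimately reduce the estimate, so the
#' result may be negative for sub-1 G windows.
#'
#' @param trace An [accel_trace()].
#' @param k_index,l_index 1-based sample indices, `1 <= k_index < l_index <=
#'   length(trace)`.
#' @param g_mps2 Conversion from G to m/s^2 (default standard gravity,
#'   9.80665).
#' @return Signed velocity in m/s.
#' @export
reference_velocity <- function(trace, k_index, l_index, g_mps2 = 9.80665) {
  stopifnot(inherits(trace, "accel_trace"))
  n <- length(trace$ax)
  k_index <- as.integer(k_index); l_index <- as.integer(l_index)
  if (is.na(k_index) || is.na(l_index) || k_index < 1L || l_index > n ||
      k_index >= l_index)
    stopf("invalid window: need 1 <= k_index < l_index <= %d", n)
  idx <- k_index:l_index
  svm <- svm_xyz(trace$ax[idx], trace$ay[idx], trace$az[idx])
  t <- trace$t0 + (idx - 1) / trace$sample_rate_hz
  pracma::trapz(t, (svm - 1) * g_mps2)
}

#' Read an accelerometer trace from CSV
#'
#' Expects the dialect `t,ax,ay,az`: `t` in seconds (monotone and uniformly
#' spaced to a 1e-6 s tolerance), axes in G, '.' decimal separator.
#' Irregularly sampled input is rejected; resampling is out of scope.
#'
#' @param path Path to a CSV file.
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stopf("accelerometer CSV must have columns t,ax,ay,az (got: %s)",
          paste(names(df), collapse = ","))
  t <- as.numeric(df$t)
  if (length(t) < 1L) stopf("empty trace in %s", path)
  if (length(t) >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0)) stopf("time column must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      stopf("non-uniform sampling (spread %.3g s > 1e-6 s); resample before loading",
            max(dt) - min(dt))
    sr <- 1 / mean(dt)
  } else {
    sr <- 200
  }
  accel_trace(df$ax, df$ay, df$az, sample_rate_hz = sr, t0 = t[1])
}

#' Write an accelerometer trace to CSV
#'
#' Inverse of [read_accel_csv()]; writes the `t,ax,ay,az` dialect.
#'
#' @param trace An [accel_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- data.frame(t = trace_times(trace),
                   ax = trace$ax, ay = trace$ay, az = trace$az)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
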