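#' Log-distance path-loss parameters
#'
#' The log-distance model gives the received power at distance d as
#' `pl_d0 - 10 * n * log10(d / d0) + X`, where `n` is the path-loss
#' exponent (2 in free space), `pl_d0` the received power at the reference
#' distance `d0`, and `X` a zero-mean Gaussian shadowing term with standard
#' deviation `sigma` dB capturing indoor interference.
#'
#' @param n Path-loss exponent (> 0, default 2, free space).
#' @param pl_d0 Received power at `d0` in dBm (default -40, a typical
#'   2.4 GHz short-range value).
#' @param d0 Reference distance in meters (> 0, default 1).
#' @param sigma Shadowing standard deviation in dB (>= 0, default 0 for
#'   deterministic use).
#' @return An object of class `path_loss_params`.
#' @export
path_loss_params <- function(n = 2.0, pl_d0 = -40, d0 = 1.0, sigma = 0) {
  if (n <= 0) stopf("path-loss exponent n must be > 0")
  if (d0 <= 0) stopf("reference distance d0 must be > 0")
  if (sigma < 0) stopf("shadowing sigma must be >= 0")
  structure(list(n = n, pl_d0 = pl_d0, d0 = d0, sigma = sigma),
            class = "path_loss_params")
}

#' Received power from the log-distance path-loss model
#'
#' @param distance Distance(s) in meters, > 0. Vectorized.
#' @param params A [path_loss_params()].
#' @param noise_draw Shadowing draw(s) in dB to add, or NULL for none. The
#'   draw is supplied by the caller so the model itself stays deterministic.
#' @return Received power in dBm; strictly decreasing in distance when the
#'   noise is zero.
#' @export
path_loss_power <- function(distance, params = path_loss_params(),
                            noise_draw = NULL) {
  stopifnot(inherits(params, "path_loss_params"))
  if (any(!is.finite(distance)) || any(distance <= 0))
    stopf("invalid geometry: distance must be finite and > 0")
  p <- params$pl_d0 - 10 * params$n * log10(distance / params$d0)
  if (!is.null(noise_draw)) p <- p + noise_draw
  p
}

#' Map received power (dBm) to the 0-255 RSSI scale
#'
#' The radio reports signal strength as an integer 0-255 obtained linearly
#' from the received power: `round(slope * power + intercept)`, clamped to
#' the scale. A positive slope is required so that stronger signals map to
#' larger RSSI.
#'
#' @param power Received power in dBm. Vectorized.
#' @param slope RSSI units per dB (> 0).
#' @param intercept RSSI units.
#' @return Integer RSSI value(s) on 0-255.
#' @export
dbm_to_rssi <- function(power, slope, intercept) {
  if (any(!is.finite(power))) stopf("invalid power: non-finite dBm value")
  if (!is.finite(slope) || slope <= 0)
    stopf("invalid calibration: slope must be > 0")
  as.integer(clamp(round(slope * power + intercept), 0, 255))
}

#' Calibrate the dBm-to-RSSI line from class anchors
#'
#' The radio's own linear coefficients are not published, so the map is
#' fitted to the distance semantics of the RSSI classes: signals measured
#' within 0.5 m fall at the Class I lower edge (RSSI 144) and signals from
#' 7 m and beyond at the Class III/IV boundary (RSSI 60). The unique line
#' through the two (noise-free power, RSSI) anchors reproduces that
#' correspondence for any path-loss parameters.
#'
#' @param params A [path_loss_params()] (`sigma` is ignored).
#' @param anchors Named list with `near`/`far` distances in meters and
#'   `rssi_near`/`rssi_far` values; defaults 0.5 m -> 144, 7 m -> 60.
#' @return List with `slope` (RSSI/dB, > 0) and `intercept`.
#' @export
calibrate_rssi_map <- function(params = path_loss_params(),
                               anchors = list(near = 0.5, far = 7,
                                              rssi_near = 144, rssi_far = 60)) {
  p_near <- path_loss_power(anchors$near, params)
  p_far <- path_loss_power(anchors$far, params)
  if (abs(p_near - p_far) < 1e-12)
    stopf("calibration error: anchor powers are equal (degenerate fit)")
  slope <- (anchors$rssi_near - anchors$rssi_far) / (p_near - p_far)
  intercept <- anchors$rssi_near - slope * p_near
  list(slope = slope, intercept = intercept)
}

#' RSSI class table
#'
#' Partition of the 0-255 RSSI scale into four distance classes together
#' with the parameters of the piecewise-linear weighting transform
#' `rss' = A + ratio * (rss - B)`. The default is the 25 degC table:
#' Class I (144-255) for readings within 0.5 m, Class II (112-143) for
#' 0.5-2 m, Class III (61-111) for 2-7 m, Class IV (0-60) for 7 m and
#' beyond, with (A, ratio, B) = (176, 0.05, 144), (112, 0.3, 112),
#' (60, 0.6, 60) and (0, 1, 0). The printed class ranges meet at 60; the
#' boundary value is assigned to Class IV, where both parameterizations
#' give the identical weighted value 60. Alternative tables (e.g. for other
#' temperatures) can be supplied as a data.frame of the same shape.
#'
#' @param classes Optional data.frame with columns `class`, `rssi_lo`,
#'   `rssi_hi`, `A`, `ratio`, `B` replacing the default table.
#' @return A data.frame of class `rssi_class_table`.
#' @export
rssi_class_table <- function(classes = NULL) {
  if (is.null(classes)) {
    classes <- data.frame(
      class   = c("I", "II", "III", "IV"),
      rssi_lo = c(144L, 112L, 61L, 0L),
      rssi_hi = c(255L, 143L, 111L, 60L),
      A       = c(176, 112, 60, 0),
      ratio   = c(0.05, 0.3, 0.6, 1),
      B       = c(144, 112, 60, 0),
      stringsAsFactors = FALSE)
  }
  need <- c("class", "rssi_lo", "rssi_hi", "A", "ratio", "B")
  if (!all(need %in% names(classes)))
    stopf("class table needs columns: %s", paste(need, collapse = ", "))
  classes <- classes[order(classes$rssi_lo), need]
  classes$class <- as.character(classes$class)
  classes$rssi_lo <- as.integer(classes$rssi_lo)
  classes$rssi_hi <- as.integer(classes$rssi_hi)
  for (col in c("A", "ratio", "B")) classes[[col]] <- as.numeric(classes[[col]])
  covered <- unlist(mapply(seq, classes$rssi_lo, classes$rssi_hi,
                           SIMPLIFY = FALSE))
  if (length(covered) != 256L || !identical(sort(covered), 0:255))
    stopf("class ranges must partition 0-255 exactly")
  if (any(classes$ratio <= 0))
    stopf("class ratio must be > 0 (transform must increase within class)")
  w_lo <- classes$A + classes$ratio * (classes$rssi_lo - classes$B)
  w_hi <- classes$A + classes$ratio * (classes$rssi_hi - classes$B)
  if (any(diff(c(rbind(w_lo, w_hi))) <= 0))
    stopf("weighted transform must be strictly increasing across class boundaries")
  rownames(classes) <- NULL
  class(classes) <- c("rssi_class_table", "data.frame")
  classes
}

#' Read / write an RSSI class table as JSON
#'
#' Serialization: `{"classes": [{"name", "rssi_lo", "rssi_hi", "A",
#' "ratio", "B"}, ...]}`. The default table round-trips bit-exactly.
#'
#' @param path JSON file path.
#' @return For the reader, an [rssi_class_table()]; the writer returns
#'   `path` invisibly.
#' @export
read_class_table_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  df <- obj$classes
  names(df)[names(df) == "name"] <- "class"
  rssi_class_table(df)
}

#' @rdname read_class_table_json
#' @param table An [rssi_class_table()] to serialize.
#' @export
write_class_table_json <- function(table, path) {
  stopifnot(inherits(table, "rssi_class_table"))
  df <- as.data.frame(table)
  names(df)[names(df) == "class"] <- "name"
  jsonlite::write_json(list(classes = df), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

row_for_rssi <- function(rss, table) {
  if (any(!is.finite(rss)) || any(rss < 0) || any(rss > 255) ||
      any(rss != round(rss)))
    stopf("invalid RSSI: values must be integers on 0-255")
  idx <- vapply(rss, function(v)
    which(v >= table$rssi_lo & v <= table$rssi_hi)[1], integer(1))
  idx
}

#' Classify a raw RSSI value
#'
#' @param rss Integer RSSI value(s) on 0-255. Vectorized.
#' @param table An [rssi_class_table()].
#' @return Class label(s) ("I".."IV" for the default table).
#' @export
classify_rssi <- function(rss, table = rssi_class_table()) {
  stopifnot(inherits(table, "rssi_class_table"))
  table$class[row_for_rssi(rss, table)]
}

#' Weighted RSSI transform
#'
#' Applies the class-dependent linear adjustment `rss' = A + ratio *
#' (rss - B)` that compresses the noisy near-field classes and stretches
#' the scale so that Euclidean distances in RSSI space better reflect
#' physical proximity. Strictly increasing over the whole 0-255 domain.
#'
#' @param rss Integer RSSI value(s) on 0-255. Vectorized.
#' @param table An [rssi_class_table()].
#' @return Real-valued weighted RSSI.
#' @export
weight_rssi <- function(rss, table = rssi_class_table()) {
  stopifnot(inherits(table, "rssi_class_table"))
  i <- row_for_rssi(rss, table)
  table$A[i] + table$ratio[i] * (rss - table$B[i])
}
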