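#' Node layout of a deployment
#'
#' Describes one planar room: its bounds, the fixed reference nodes (known
#' coordinates, observed RSSI), the RF generators (broadcasters) and the
#' gateway. Coordinates are meters with the origin at a room corner and x
#' along the length axis.
#'
#' @param room_length,room_width Room dimensions in meters (> 0).
#' @param reference_nodes data.frame with columns `id`, `x`, `y`; ids
#'   unique, coordinates inside the room. At least one node.
#' @param rf_generators data.frame with columns `id`, `x`, `y`; at least
#'   one generator.
#' @param gateway Numeric `c(x, y)` of the gateway.
#' @return An object of class `node_layout`.
#' @export
node_layout <- function(room_length, room_width, reference_nodes,
                        rf_generators, gateway) {
  if (room_length <= 0 || room_width <= 0)
    stopf("room dimensions must be > 0")
  check_nodes <- function(df, what) {
    if (!all(c("id", "x", "y") %in% names(df)) || nrow(df) < 1)
      stopf("%s must be a data.frame with columns id, x, y and >= 1 row", what)
    if (anyDuplicated(df$id)) stopf("%s ids must be unique", what)
    if (any(df$x < 0 | df$x > room_length | df$y < 0 | df$y > room_width))
      stopf("%s coordinates must lie within the room bounds", what)
    df$id <- as.character(df$id)
    df[, c("id", "x", "y")]
  }
  reference_nodes <- check_nodes(reference_nodes, "reference_nodes")
  rf_generators <- check_nodes(rf_generators, "rf_generators")
  gateway <- as.numeric(gateway)
  if (length(gateway) != 2 || any(gateway < 0) ||
      gateway[1] > room_length || gateway[2] > room_width)
    stopf("gateway must be c(x, y) within the room")
  structure(list(room = c(length = room_length, width = room_width),
                 reference_nodes = reference_nodes,
                 rf_generators = rf_generators,
                 gateway = gateway),
            class = "node_layout")
}

#' @export
print.node_layout <- function(x, ...) {
  cat(sprintf("node_layout: %.2f x %.2f m room, %d reference nodes, %d generators\n",
              x$room["length"], x$room["width"],
              nrow(x$reference_nodes), nrow(x$rf_generators)))
  invisible(x)
}

#' Read / write a node layout (JSON or YAML)
#'
#' Format: `{"room": {"length", "width"}, "reference_nodes":
#' [{"id","x","y"}...], "rf_generators": [...], "gateway": {"x","y"}}`.
#'
#' @param path File path; `.json` or `.yaml`/`.yml`.
#' @return For the reader, a [node_layout()]; the writer returns `path`
#'   invisibly.
#' @export
read_layout <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  as_df <- function(x) {
    if (is.data.frame(x)) x else do.call(rbind, lapply(x, as.data.frame))
  }
  node_layout(obj$room$length, obj$room$width,
              as_df(obj$reference_nodes), as_df(obj$rf_generators),
              c(obj$gateway$x, obj$gateway$y))
}

#' @rdname read_layout
#' @param layout A [node_layout()] to serialize.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "node_layout"))
  obj <- list(room = list(length = unname(layout$room["length"]),
                          width = unname(layout$room["width"])),
              reference_nodes = layout$reference_nodes,
              rf_generators = layout$rf_generators,
              gateway = list(x = layout$gateway[1], y = layout$gateway[2]))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    df2list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    obj$reference_nodes <- df2list(obj$reference_nodes)
    obj$rf_generators <- df2list(obj$rf_generators)
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' One RSSI collection round
#'
#' Holds the observations of a single collection round: the wearable's RSSI
#' vector over the N generators and the M x N matrix of every reference
#' node's RSSI over the same generators. `weighted` is filled by
#' [weight_round()] and starts NULL.
#'
#' @param wearable Integer RSSI vector of length N (named by generator id
#'   if available).
#' @param references Integer M x N matrix (rownames = reference ids,
#'   colnames = generator ids).
#' @return An object of class `rssi_round`.
#' @export
rssi_round <- function(wearable, references) {
  references <- as.matrix(references)
  if (length(wearable) < 1 || ncol(references) != length(wearable))
    stopf("dimension error: references must be M x N with N = length(wearable)")
  chk <- c(wearable, references)
  if (any(!is.finite(chk)) || any(chk < 0) || any(chk > 255) ||
      any(chk != round(chk)))
    stopf("invalid RSSI: raw entries must be integers on 0-255")
  structure(list(wearable = as.integer(wearable) |>
                   stats::setNames(names(wearable)),
                 references = references, weighted = NULL),
            class = "rssi_round")
}

#' Read / write an RSSI round as CSV
#'
#' Dialect: `observer_id,generator_id,rssi`, one row per observation, with
#' observer_id "wearable" for the wearable sensor. Integer round-trip is
#' bit-exact.
#'
#' @param path CSV file path.
#' @return For the reader, an [rssi_round()]; the writer returns `path`
#'   invisibly.
#' @export
read_round_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "generator_id", "rssi")
  if (!all(need %in% names(df)))
    stopf("RSSI round CSV needs columns: %s", paste(need, collapse = ","))
  gens <- unique(df$generator_id)
  w <- df[df$observer_id == "wearable", ]
  refs <- df[df$observer_id != "wearable", ]
  ref_ids <- unique(refs$observer_id)
  mat <- matrix(NA_integer_, length(ref_ids), length(gens),
                dimnames = list(ref_ids, gens))
  mat[cbind(match(refs$observer_id, ref_ids),
            match(refs$generator_id, gens))] <- refs$rssi
  wv <- stats::setNames(w$rssi[match(gens, w$generator_id)], gens)
  rssi_round(wv, mat)
}

#' @rdname read_round_csv
#' @param round An [rssi_round()] to serialize.
#' @export
write_round_csv <- function(round, path) {
  stopifnot(inherits(round, "rssi_round"))
  gens <- colnames(round$references) %||% paste0("G", seq_along(round$wearable))
  refs <- rownames(round$references) %||%
    paste0("R", seq_len(nrow(round$references)))
  df <- rbind(
    data.frame(observer_id = "wearable", generator_id = gens,
               rssi = as.integer(round$wearable)),
    data.frame(observer_id = rep(refs, times = length(gens)),
               generator_id = rep(gens, each = length(refs)),
               rssi = as.integer(round$references)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Euclidean distance between two RSSI vectors
#'
#' Similarity measure in RSSI space between the wearable and one reference
#' node: the smaller the distance, the more alike the two nodes' radio
#' views, hence the closer they are assumed to be physically.
#'
#' @param w,r_i Equal-length numeric vectors (raw or weighted RSSI).
#' @return Non-negative distance.
#' @export
rssi_distance <- function(w, r_i) {
  if (length(w) != length(r_i) || length(w) < 1)
    stopf("dimension error: RSSI vectors must have equal length >= 1")
  sqrt(sum((w - r_i)^2))
}

#' Apply the weighted-RSSI transform to a round
#'
#' Fills `round$weighted` with element-wise [weight_rssi()] copies of the
#' wearable vector and reference matrix; raw entries are left untouched.
#' Applying it to an already-weighted round is an error (weighted values
#' are reals outside the raw 0-255 contract).
#'
#' @param round An [rssi_round()].
#' @param table An [rssi_class_table()].
#' @return The round with `weighted` filled.
#' @export
weight_round <- function(round, table = rssi_class_table()) {
  stopifnot(inherits(round, "rssi_round"))
  if (!is.null(round$weighted))
    stopf("round is already weighted; weight_round is not idempotent by contract")
  wmat <- matrix(weight_rssi(as.vector(round$references), table),
                 nrow = nrow(round$references),
                 dimnames = dimnames(round$references))
  round$weighted <- list(
    wearable = stats::setNames(weight_rssi(as.integer(round$wearable), table),
                               names(round$wearable)),
    references = wmat)
  round
}

#' Estimate the wearable position by weighted p-nearest neighbors
#'
#' Computes the RSSI-space Euclidean distance between the wearable and
#' every reference node (on weighted RSSI by default), selects the p
#' nearest nodes, and returns the weighted centroid of their coordinates
#' with normalized inverse-square weights `w_k = (1/e_k^2) / sum(1/e_i^2)`,
#' so the node with the smallest distance has the largest weight. Nodes at
#' exactly zero RSSI-distance take the entire weight mass (split equally),
#' the limiting case of inverse-square weighting. Ties at the p-th smallest
#' distance are broken by ascending reference-node id.
#'
#' @param round An [rssi_round()].
#' @param layout The matching [node_layout()].
#' @param p Number of nearest reference nodes to combine (default 4, the
#'   error-minimizing choice in the deployment this package models).
#' @param use_weighting Use the weighted-RSSI transform before the distance
#'   computation (default TRUE). If the round is not yet weighted it is
#'   weighted on the fly with `table`.
#' @param table An [rssi_class_table()] for on-the-fly weighting.
#' @return An object of class `position_estimate`: list with `x`, `y`
#'   (meters), `p`, `neighbors` (data.frame id, distance, weight) and
#'   `distances` (named vector over all reference nodes).
#' @export
estimate_position <- function(round, layout, p = 4, use_weighting = TRUE,
                              table = rssi_class_table()) {
  stopifnot(inherits(round, "rssi_round"), inherits(layout, "node_layout"))
  nodes <- layout$reference_nodes
  m <- nrow(nodes)
  if (p < 1 || p > m)
    stopf("configuration error: p must satisfy 1 <= p <= M (= %d)", m)
  if (use_weighting) {
    if (is.null(round$weighted)) round <- weight_round(round, table)
    wv <- round$weighted$wearable
    rm_ <- round$weighted$references
  } else {
    wv <- round$wearable
    rm_ <- round$references
  }
  if (nrow(rm_) != m)
    stopf("dimension error: round has %d reference rows, layout has %d nodes",
          nrow(rm_), m)
  e <- sqrt(rowSums((rm_ - matrix(wv, m, length(wv), byrow = TRUE))^2))
  ids <- rownames(rm_) %||% nodes$id
  ord <- order(e, ids)
  sel <- ord[seq_len(p)]
  es <- e[sel]
  if (any(es == 0)) {
    w <- as.numeric(es == 0) / sum(es == 0)
  } else {
    inv <- 1 / es^2
    w <- inv / sum(inv)
  }
  ni <- match(ids[sel], nodes$id)
  structure(list(
    x = sum(w * nodes$x[ni]),
    y = sum(w * nodes$y[ni]),
    p = as.integer(p),
    neighbors = data.frame(id = ids[sel], distance = es, weight = w,
                           stringsAsFactors = FALSE, row.names = NULL),
    distances = stats::setNames(e, ids)),
    class = "position_estimate")
}

#' @export
print.position_estimate <- function(x, ...) {
  cat(sprintf("position_estimate: (%.3f, %.3f) m from %d neighbors\n",
              x$x, x$y, x$p))
  invisible(x)
}

#' Write a position estimate as JSON
#'
#' Format: `{"x", "y", "p", "neighbors": [{"id","distance","weight"}...]}`.
#'
#' @param estimate A `position_estimate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(estimate, path) {
  stopifnot(inherits(estimate, "position_estimate"))
  jsonlite::write_json(list(x = estimate$x, y = estimate$y, p = estimate$p,
                            neighbors = estimate$neighbors),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Planar error distance between estimate and truth
#'
#' @param estimate Numeric `c(x, y)` or a `position_estimate`.
#' @param truth Numeric `c(x, y)` of the true position.
#' @return Euclidean distance in meters.
#' @export
error_distance <- function(estimate, truth) {
  if (inherits(estimate, "position_estimate"))
    estimate <- c(estimate$x, estimate$y)
  estimate <- as.numeric(estimate); truth <- as.numeric(truth)
  if (length(estimate) != 2 || length(truth) != 2 ||
      any(!is.finite(c(estimate, truth))))
    stopf("positions must be finite c(x, y) pairs")
  sqrt(sum((estimate - truth)^2))
}
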