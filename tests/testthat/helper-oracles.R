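# Independent brute-force oracles used to cross-check the package
# implementations. Deliberately naive: scalar loops, explicit if-chains,
# full sorts.

# Scalar-loop feature oracle.
oracle_features <- function(trace) {
  n <- length(trace$ax)
  sxyz <- numeric(n); sxz <- numeric(n)
  for (i in seq_len(n)) {
    sxyz[i] <- sqrt(trace$ax[i]^2 + trace$ay[i]^2 + trace$az[i]^2)
    sxz[i] <- sqrt(trace$ax[i]^2 + trace$az[i]^2)
  }
  list(svm_xyz = sxyz, svm_xz = sxz)
}

# Scalar weighted-RSSI oracle for the 25 degC table, written as an
# explicit if-chain straight from the printed parameter rows.
oracle_weight <- function(rss) {
  if (rss >= 144) 176 + 0.05 * (rss - 144)
  else if (rss >= 112) 112 + 0.3 * (rss - 112)
  else if (rss >= 61) 60 + 0.6 * (rss - 60)
  else 0 + 1 * (rss - 0)
}

# Naive weighted p-nearest-neighbor estimate: loops, full sort, weights
# recomputed from first principles.
oracle_estimate <- function(round, layout, p, use_weighting) {
  nodes <- layout$reference_nodes
  m <- nrow(nodes)
  nN <- length(round$wearable)
  w <- as.numeric(round$wearable)
  R <- matrix(as.numeric(round$references), m, nN)
  if (use_weighting) {
    w <- vapply(w, oracle_weight, numeric(1))
    for (i in seq_len(m)) for (j in seq_len(nN)) R[i, j] <- oracle_weight(R[i, j])
  }
  e <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(nN)) s <- s + (w[j] - R[i, j])^2
    e[i] <- sqrt(s)
  }
  ids <- rownames(round$references)
  if (is.null(ids)) ids <- nodes$id
  ord <- order(e, ids)
  sel <- ord[1:p]
  es <- e[sel]
  if (any(es == 0)) {
    wt <- ifelse(es == 0, 1 / sum(es == 0), 0)
  } else {
    wt <- (1 / es^2) / sum(1 / es^2)
  }
  ni <- match(ids[sel], nodes$id)
  c(x = sum(wt * nodes$x[ni]), y = sum(wt * nodes$y[ni]))
}

# Random short trace with accelerations in [-4, 4] G.
random_trace <- function(n = 10, sr = 200) {
  accel_trace(stats::runif(n, -4, 4), stats::runif(n, -4, 4),
              stats::runif(n, -4, 4), sample_rate_hz = sr)
}

# Random localization instance: layout, wearable round, p.
random_instance <- function() {
  m <- sample(2:18, 1)
  nN <- sample(1:5, 1)
  L <- 11; W <- 5.75
  nodes <- data.frame(id = sprintf("R%02d", 1:m),
                      x = stats::runif(m, 0, L), y = stats::runif(m, 0, W))
  gens <- data.frame(id = sprintf("G%d", 1:nN),
                     x = stats::runif(nN, 0, L), y = stats::runif(nN, 0, W))
  lay <- node_layout(L, W, nodes, gens, c(L / 2, W / 2))
  refs <- matrix(sample(0:255, m * nN, replace = TRUE), m, nN,
                 dimnames = list(nodes$id, gens$id))
  rnd <- rssi_round(stats::setNames(sample(0:255, nN, replace = TRUE), gens$id),
                    refs)
  list(layout = lay, round = rnd, p = sample(1:min(6, m), 1))
}

# Hand-built slump trace: quiet, then m_slump samples at constant svm
# `peak` with horizontal fraction hf, then quiet rest. K is the first
# slump sample; the closed-form reference velocity over [K, L] is
# g * dt * ((peak - 1) * (m_slump - 1) + (peak + 1) / 2 - 1).
slump_trace <- function(peak = 3.2, hf = 0.7, m_slump = 19, sr = 200,
                        n_pre = 100, n_rest = 200) {
  ax <- c(rep(0, n_pre), rep(peak * hf, m_slump), rep(0, n_rest))
  ay <- c(rep(1, n_pre), rep(peak * sqrt(1 - hf^2), m_slump), rep(1, n_rest))
  az <- rep(0, n_pre + m_slump + n_rest)
  list(trace = accel_trace(ax, ay, az, sample_rate_hz = sr),
       k = n_pre + 1L, l = n_pre + m_slump + 1L,
       v_closed = 9.80665 * (1 / sr) *
         ((peak - 1) * (m_slump - 1) + (peak + 1) / 2 - 1))
}
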