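test_that("RSSI-space distance matches hand values and is permutation-stable", {
  expect_equal(rssi_distance(c(3, 7), c(3, 7)), 0.0)
  expect_equal(rssi_distance(c(3, 0), c(0, 4)), 5.0)
  perm <- c(2, 1, 3)
  w <- c(10, 20, 30); r <- c(12, 25, 28)
  expect_equal(rssi_distance(w[perm], r[perm]), rssi_distance(w, r))
  expect_error(rssi_distance(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("weighting a round matches the scalar oracle and is single-shot", {
  set.seed(5)
  refs <- matrix(sample(0:255, 12), 4, 3,
                 dimnames = list(paste0("R", 1:4), paste0("G", 1:3)))
  rnd <- rssi_round(stats::setNames(sample(0:255, 3), paste0("G", 1:3)), refs)
  wr <- weight_round(rnd)
  expect_equal(as.vector(wr$weighted$references),
               vapply(as.vector(refs), oracle_weight, numeric(1)))
  expect_equal(unname(wr$weighted$wearable),
               vapply(as.integer(rnd$wearable), oracle_weight, numeric(1)))
  # raw entries untouched
  expect_identical(wr$references, rnd$references)
  expect_error(weight_round(wr), "already weighted")
  # all-144 matrix maps to all 176
  rnd144 <- rssi_round(rep(144L, 3), matrix(144L, 4, 3))
  expect_true(all(weight_round(rnd144)$weighted$references == 176))
  expect_error(rssi_round(c(1, 2), matrix(c(0, 300, 1, 2, 3, 4), 3, 2)),
               "invalid RSSI")
})

test_that("degenerate estimates recover exact geometry", {
  lay <- grid_layout(11, 5.75, 2, 5)
  rnd <- simulate_round(lay, c(lay$reference_nodes$x[7],
                               lay$reference_nodes$y[7]),
                        path_loss_params(sigma = 0))
  # wearable co-located with node 7: its row matches the wearable vector
  expect_equal(unname(rnd$wearable),
               unname(rnd$references["R07", ]))
  est <- estimate_position(rnd, lay, p = 1)
  expect_equal(est$x, lay$reference_nodes$x[7])
  expect_equal(est$y, lay$reference_nodes$y[7])
  expect_equal(est$neighbors$id, "R07")

  # all distances equal: uniform weights give the centroid
  m <- nrow(lay$reference_nodes)
  rnd_eq <- rssi_round(rep(100L, 3), matrix(90L, m, 3,
                                            dimnames = list(lay$reference_nodes$id,
                                                            paste0("G", 1:3))))
  est_eq <- estimate_position(rnd_eq, lay, p = m, use_weighting = FALSE)
  expect_equal(est_eq$x, mean(lay$reference_nodes$x))
  expect_equal(est_eq$y, mean(lay$reference_nodes$y))
  expect_equal(est_eq$neighbors$weight, rep(1 / m, m))

  expect_error(estimate_position(rnd_eq, lay, p = m + 1), "configuration")
})

test_that("estimates agree with the brute-force oracle and stay in the neighbor hull", {
  set.seed(99)
  for (rep in 1:40) {
    inst <- random_instance()
    for (uw in c(TRUE, FALSE)) {
      est <- estimate_position(inst$round, inst$layout, p = inst$p,
                               use_weighting = uw)
      orc <- oracle_estimate(inst$round, inst$layout, inst$p, uw)
      expect_equal(est$x, unname(orc["x"]), tolerance = 1e-12)
      expect_equal(est$y, unname(orc["y"]), tolerance = 1e-12)
      # weights normalized and non-increasing with distance
      expect_equal(sum(est$neighbors$weight), 1, tolerance = 1e-9)
      expect_true(all(diff(est$neighbors$weight) <= 1e-12))
      # convex combination stays inside the neighbor bounding box
      ni <- match(est$neighbors$id, inst$layout$reference_nodes$id)
      xs <- inst$layout$reference_nodes$x[ni]
      ys <- inst$layout$reference_nodes$y[ni]
      expect_true(est$x >= min(xs) - 1e-12 && est$x <= max(xs) + 1e-12)
      expect_true(est$y >= min(ys) - 1e-12 && est$y <= max(ys) + 1e-12)
    }
  }
})

test_that("estimates are equivariant under translating the whole layout", {
  set.seed(7)
  inst <- random_instance()
  est <- estimate_position(inst$round, inst$layout, p = inst$p)
  dx <- 3; dy <- 1.5
  lay2 <- node_layout(inst$layout$room["length"] + dx,
                      inst$layout$room["width"] + dy,
                      transform(inst$layout$reference_nodes,
                                x = x + dx, y = y + dy),
                      transform(inst$layout$rf_generators,
                                x = x + dx, y = y + dy),
                      inst$layout$gateway + c(dx, dy))
  est2 <- estimate_position(inst$round, lay2, p = inst$p)
  expect_equal(est2$x, est$x + dx)
  expect_equal(est2$y, est$y + dy)
})

test_that("error distance is a planar metric", {
  expect_equal(error_distance(c(1, 1), c(1, 1)), 0.0)
  expect_equal(error_distance(c(0, 0), c(3, 4)), 5.0)
  expect_equal(error_distance(c(2, 5), c(7, 1)), error_distance(c(7, 1), c(2, 5)))
  est <- structure(list(x = 3, y = 4), class = "position_estimate")
  expect_equal(error_distance(est, c(0, 0)), 5.0)
  expect_error(error_distance(c(NA, 1), c(0, 0)), "finite")
})

test_that("rounds and layouts round-trip through their file formats", {
  lay <- grid_layout(6, 4, 2, 3)
  rnd <- simulate_round(lay, c(3, 2), path_loss_params(sigma = 2), seed = 8)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_round_csv(rnd, csv)
  back <- read_round_csv(csv)
  expect_identical(back$references, rnd$references)
  expect_identical(back$wearable, rnd$wearable)

  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_layout(lay, path)
    lay2 <- read_layout(path)
    expect_equal(lay2$reference_nodes, lay$reference_nodes)
    expect_equal(lay2$rf_generators, lay$rf_generators)
    expect_equal(unname(lay2$room), unname(lay$room))
  }

  est <- estimate_position(rnd, lay, p = 2)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_estimate_json(est, jpath)
  obj <- jsonlite::fromJSON(jpath)
  expect_equal(obj$x, est$x)
  expect_equal(obj$neighbors$id, est$neighbors$id)
})
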