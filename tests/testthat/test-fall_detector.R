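test_that("detector config enforces threshold ordering and positivity", {
  expect_s3_class(detector_config(), "detector_config")
  expect_error(detector_config(th_low_xyz = 7), "below th_high_xyz")
  expect_error(detector_config(th_xz = -1), "> 0")
  expect_error(detector_config(rest_window_s = 3), "smaller than search_window_s")
})

test_that("impact bursts are classified by the dominant phase", {
  # hard impact: critical in phase 1
  lt1 <- generate_fall_trace(fall_scenario(impact_peak = 6.5, seed = 3))
  e1 <- detect(lt1$trace)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$severity, "critical")
  expect_equal(e1$phase, 1L)
  expect_gt(e1$peak_svm_xyz, 6)

  # moderate impact with sub-threshold horizontal loading: normal, phase 2
  lt2 <- generate_fall_trace(fall_scenario(impact_peak = 4.0,
                                           horizontal_fraction = 0.45,
                                           seed = 4))
  f2 <- compute_features(lt2$trace)
  expect_lt(max(f2$svm_xz), 2)
  e2 <- detect(lt2$trace)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$severity, "normal")
  expect_equal(e2$phase, 2L)

  # slump: peak below 3.5 G but horizontal crossing + velocity -> phase 3
  s <- slump_trace(peak = 3.2, hf = 0.7, m_slump = 19)
  e3 <- detect(s$trace)
  expect_equal(nrow(e3), 1L)
  expect_equal(e3$severity, "critical")
  expect_equal(e3$phase, 3L)
  expect_equal(e3$k_index, s$k)
  expect_equal(e3$l_index, s$l)
  expect_lt(e3$k_index, e3$l_index)
  expect_equal(e3$v_max, s$v_closed, tolerance = 1e-9)
  expect_gt(e3$v_max, 1.7)

  # gravity-only trace: silence
  quiet <- accel_trace(rep(0, 600), rep(1, 600), rep(0, 600))
  expect_equal(nrow(detect(quiet)), 0L)
})

test_that("phase 3 needs a rest onset within the search window and enough velocity", {
  # no rest within 2 s of K: elevated tail instead of lying still
  s <- slump_trace(peak = 3.2, hf = 0.7, m_slump = 19, n_rest = 0)
  tail_n <- 500  # 2.5 s of residual motion outside the rest band
  tr <- accel_trace(c(s$trace$ax, rep(0.0, tail_n)),
                    c(s$trace$ay, rep(1.4, tail_n)),
                    c(s$trace$az, rep(0.0, tail_n)))
  expect_equal(nrow(detect(tr)), 0L)  # peak < 3.5 G, so no fallback alarm

  # too little velocity: short slump, rest arrives but integral < 1.7 m/s
  s2 <- slump_trace(peak = 3.2, hf = 0.7, m_slump = 5)
  expect_lt(s2$v_closed, 1.7)
  expect_equal(nrow(detect(s2$trace)), 0L)
})

test_that("alarm cancellation follows the hold and timeout rules", {
  lt <- generate_fall_trace(fall_scenario(impact_peak = 4.0,
                                          horizontal_fraction = 0.45,
                                          seed = 4))
  ev <- detect(lt$trace)
  t_ev <- ev$t[1]

  press <- function(t, hold) data.frame(press_time = t, hold_duration = hold)
  expect_equal(apply_cancellation(ev, press(t_ev + 5, 3))$status, "canceled")
  # hold too short
  expect_equal(apply_cancellation(ev, press(t_ev + 5, 1))$status, "confirmed")
  # press too late
  expect_equal(apply_cancellation(ev, press(t_ev + 31, 3))$status, "confirmed")
  # no presses at all
  expect_equal(apply_cancellation(ev)$status, "confirmed")
  expect_error(apply_cancellation(ev, press(1, -2)), "negative hold")

  # critical alarms are never canceled
  crit <- detect(generate_fall_trace(fall_scenario(impact_peak = 6.5,
                                                   seed = 3))$trace)
  expect_equal(apply_cancellation(crit, press(crit$t[1] + 1, 10))$status,
               "confirmed")
})

test_that("detection is deterministic, refractory-spaced, and monotone under scaling", {
  lt <- generate_adl_trace(adl_scenario("stairs", "fast", duration = 8, seed = 8))
  e1 <- detect(lt$trace)
  e2 <- detect(lt$trace)
  expect_identical(e1, e2)
  if (nrow(e1) > 1) {
    cfg <- detector_config()
    expect_true(all(diff(e1$trigger_index) >=
                      round(cfg$refractory_s * lt$trace$sample_rate_hz)))
  }

  # scaling a trace up can only escalate the decision
  rank_of <- function(tr) {
    ev <- detect(tr)
    if (nrow(ev) == 0) 0L else if (all(ev$severity == "normal")) 1L else 2L
  }
  base <- generate_fall_trace(fall_scenario(impact_peak = 4.0,
                                            horizontal_fraction = 0.45,
                                            seed = 4))$trace
  ranks <- vapply(c(1, 1.3, 1.8, 2.5), function(s)
    rank_of(accel_trace(base$ax * s, base$ay * s, base$az * s,
                        base$sample_rate_hz)), integer(1))
  expect_true(all(diff(ranks) >= 0))

  # traces below both entry thresholds never alarm
  set.seed(21)
  for (rep in 1:10) {
    n <- 400
    tr <- accel_trace(stats::runif(n, -0.5, 0.5),
                      stats::runif(n, 0.5, 1.5),
                      stats::runif(n, -0.5, 0.5))
    f <- compute_features(tr)
    stopifnot(max(f$svm_xyz) <= 3.5, max(f$svm_xz) <= 2)
    expect_equal(nrow(detect(tr)), 0L)
  }

  # phase 1 exactly when the trigger sample itself exceeds the high threshold
  all_ev <- rbind(detect(generate_fall_trace(fall_scenario(impact_peak = 6.5,
                                                           seed = 31))$trace),
                  detect(base))
  f_ok <- vapply(seq_len(nrow(all_ev)), function(i) {
    (all_ev$phase[i] == 1L) == (all_ev$peak_svm_xyz[i] > 6)
  }, logical(1))
  expect_true(all(f_ok))
})

test_that("events serialize to JSON lines and configs load from YAML", {
  ev <- detect(generate_fall_trace(fall_scenario(impact_peak = 6.5,
                                                 seed = 3))$trace)
  ev <- apply_cancellation(ev)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, path)
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_equal(rec$severity, "critical")
  expect_equal(rec$phase, 1L)
  expect_null(rec$v_max)
  expect_equal(rec$status, "confirmed")

  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("th_high_xyz: 7.0", "th_v: 2.0"), cfg_path)
  cfg <- read_detector_config(cfg_path)
  expect_equal(cfg$th_high_xyz, 7.0)
  expect_equal(cfg$th_v, 2.0)
  expect_equal(cfg$th_low_xyz, 3.5)  # untouched default
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_threshold: 1", bad)
  expect_error(read_detector_config(bad), "unknown")
})
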