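make_events <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(side = r[[1]], kind = r[[2]], frame = as.integer(r[[3]]),
               time_s = (as.integer(r[[3]]) - 1L) / 100, method = "manual",
               qc_flag = FALSE)
  }))
  attr(df, "usable") <- TRUE
  class(df) <- c("gait_events", class(df))
  df
}

test_that("a minimal event sequence yields one complete left cycle", {
  ev <- make_events(list("left", "foot_strike", 1), # frames 1-based: 0,50,100 -> 1,51,101
                    list("right", "foot_off", 13),
                    list("right", "foot_strike", 51),
                    list("left", "foot_off", 63),
                    list("left", "foot_strike", 101))
  cyc <- build_cycles(ev)
  left <- cyc[cyc$side == "left", ]
  expect_equal(nrow(left), 1)
  expect_true(left$valid)
  expect_equal(unlist(left[c("start", "c_off", "c_strike", "i_off", "end")]),
               c(start = 1, c_off = 13, c_strike = 51, i_off = 63, end = 101))
})

test_that("cycles missing interior events are invalid with a reason", {
  ev <- make_events(list("left", "foot_strike", 1),
                    list("right", "foot_strike", 51),
                    list("left", "foot_off", 63),
                    list("left", "foot_strike", 101))
  cyc <- build_cycles(ev)
  left <- cyc[cyc$side == "left", ]
  expect_false(left$valid)
  expect_match(left$reason, "c_off")
})

test_that("empty event lists give empty cycle lists, not errors", {
  expect_equal(nrow(build_cycles(NULL)), 0)
})

test_that("cycles overlapping an exclusion window are invalidated", {
  sim <- default_walk()
  ev <- detect_gait_events(sim$markers)
  cyc <- build_cycles(ev, exclude_windows = cbind(300, 400))
  hit <- cyc$start <= 400 & cyc$end >= 300
  expect_true(all(!cyc$valid[hit]))
  expect_true(all(cyc$valid[!hit]))
})

test_that("a 10 m walk at 0.6 m steps yields at least 6 valid cycles", {
  sim <- default_walk()
  cyc <- build_cycles(detect_gait_events(sim$markers))
  expect_gte(sum(cyc$valid), 6)
})

test_that("phase percentages follow the event-timing definitions", {
  # events at t = 0, 0.12, 0.50, 0.62, 1.00 s (100 Hz, 1-based frames)
  ev <- make_events(list("left", "foot_strike", 1),
                    list("right", "foot_off", 13),
                    list("right", "foot_strike", 51),
                    list("left", "foot_off", 63),
                    list("left", "foot_strike", 101))
  sim <- default_walk() # any trajectories; timing comes from the events
  rec <- compute_cycle_parameters(build_cycles(ev), sim$markers)
  left <- rec[rec$side == "left", ]
  expect_equal(left$stance_pct, 62)
  expect_equal(left$single_support_pct, 38)
  expect_equal(left$double_support_pct, 24)
  expect_equal(left$cadence_spm, 120)
  expect_equal(left$swing_pct, 38)
  expect_equal(left$stance_pct + left$swing_pct, 100)
})

test_that("footprint geometry gives step length, width and stride length", {
  # heel prints L(0, 0.05), R(0.60, -0.05), L(1.20, 0.05)
  sim <- generate_walk(walker_spec(step_length_m = 0.60, step_width_m = 0.10,
                                   cadence_spm = 100))
  rec <- compute_cycle_parameters(
    build_cycles(detect_gait_events(sim$markers)), sim$markers)
  rec <- rec[rec$valid, ]
  expect_equal(mean(rec$step_length_m), 0.60, tolerance = 0.002)
  expect_equal(mean(rec$step_width_m), 0.10, tolerance = 0.002)
  expect_equal(mean(rec$stride_length_m), 1.20, tolerance = 0.002)
})

test_that("perfectly periodic walking yields identical per-cycle records", {
  sim <- default_walk()
  rec <- compute_cycle_parameters(
    build_cycles(detect_gait_events(sim$markers)), sim$markers)
  agg <- aggregate_trial(rec)
  timing <- c("cadence_spm", "stance_pct", "single_support_pct",
              "double_support_pct", "stride_time_s")
  expect_true(all(agg$sd[agg$parameter %in% timing] == 0))
})

test_that("walking speed matches step length x cadence / 60 within 2%", {
  sim <- generate_walk(walker_spec(step_length_m = 0.7, cadence_spm = 96,
                                   stance_fraction = 0.61))
  rec <- compute_cycle_parameters(
    build_cycles(detect_gait_events(sim$markers)), sim$markers)
  rec <- rec[rec$valid, ]
  pred <- rec$step_length_m * rec$cadence_spm / 60
  expect_true(all(abs(rec$walking_speed_mps - pred) /
                    rec$walking_speed_mps <= 0.02))
  # phase identities per cycle
  expect_true(all(rec$stance_pct + rec$swing_pct == 100))
  expect_true(all(abs(rec$single_support_pct + rec$double_support_pct -
                        rec$stance_pct) <= 0.5))
})

test_that("parameters are invariant to lab-frame rotation and translation", {
  sim <- default_walk()
  ms <- sim$markers
  th <- 37 * pi / 180
  rot <- ms
  xs <- ms$positions[, 1, ]; ys <- ms$positions[, 2, ]
  rot$positions[, 1, ] <- cos(th) * xs - sin(th) * ys + 5
  rot$positions[, 2, ] <- sin(th) * xs + cos(th) * ys - 3
  rec1 <- compute_cycle_parameters(build_cycles(detect_gait_events(ms)), ms)
  rec2 <- compute_cycle_parameters(build_cycles(detect_gait_events(rot)), rot)
  for (p in c("step_length_m", "step_width_m", "cadence_spm",
              "walking_speed_mps", "stance_pct")) {
    expect_equal(rec2[[p]], rec1[[p]], tolerance = 1e-8)
  }
})

test_that("trial aggregation returns means, n-1 SDs and cycle counts", {
  rec <- data.frame(step_length_m = c(0.60, 0.62), valid = TRUE)
  agg <- aggregate_trial(rec)
  expect_equal(agg$mean, 0.61)
  expect_equal(agg$sd, sd(c(0.60, 0.62))) # ~0.01414
  expect_equal(agg$n, 2L)
  # single cycle: SD undefined, reported missing
  one <- aggregate_trial(data.frame(step_length_m = 0.6, valid = TRUE))
  expect_true(is.na(one$sd))
  # identical cycles: SD zero
  same <- aggregate_trial(data.frame(step_length_m = c(0.6, 0.6),
                                     valid = TRUE))
  expect_equal(same$sd, 0)
  # zero valid cycles: trial excluded
  expect_error(aggregate_trial(data.frame(step_length_m = 1,
                                          valid = FALSE)), "excluded")
})
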