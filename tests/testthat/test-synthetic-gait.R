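test_that("walker spec validates its parameters and derives identities", {
  s <- walker_spec(step_length_m = 0.60, cadence_spm = 100)
  expect_equal(s$speed_mps, 0.60 * 100 / 60) # = 1.0 m/s
  expect_equal(s$double_support_fraction, 2 * s$stance_fraction - 1)
  s2 <- walker_spec(stance_fraction = 0.62)
  expect_equal(s2$double_support_fraction, 0.24) # 24 %GC

  expect_error(walker_spec(stance_fraction = 0.45), "stance_fraction")
  expect_error(walker_spec(stance_fraction = 0.80), "stance_fraction")
  expect_error(walker_spec(step_length_m = -1), "step_length_m")
  expect_error(walker_spec(dropout_rate = 1), "dropout_rate")
})

test_that("ground-truth events increase in frame and alternate sides per kind", {
  sim <- default_walk()
  ev <- sim$truth$events
  expect_true(all(diff(ev$frame) >= 0))
  for (kind in c("foot_strike", "foot_off")) {
    sides <- ev$side[ev$kind == kind]
    expect_true(all(sides[-1] != sides[-length(sides)]))
  }
})

test_that("stance feet are exactly stationary in the horizontal plane", {
  sim <- default_walk()
  ev <- sim$truth$events
  pos <- marker_xyz(sim$markers, "LHEE")
  st <- ev$frame[ev$side == "left" & ev$kind == "foot_strike"]
  off <- ev$frame[ev$side == "left" & ev$kind == "foot_off"]
  for (s in st[1:3]) {
    o <- off[off > s][1]
    span <- pos[s:o, 1:2]
    expect_lt(max(apply(span, 2, function(v) diff(range(v)))), 1e-9)
    expect_lt(max(abs(pos[s:o, 3])), 1e-9) # heel on the ground
  }
})

test_that("ground-truth per-cycle parameters match the closed-form identities", {
  sim <- generate_walk(walker_spec(step_length_m = 0.65, cadence_spm = 110,
                                   stance_fraction = 0.64))
  cyc <- sim$truth$cycles
  expect_equal(unique(cyc$walking_speed_mps), 0.65 * 110 / 60)
  expect_equal(unique(cyc$cadence_spm), 110)
  expect_equal(unique(cyc$stance_pct), 64)
  expect_equal(unique(cyc$double_support_pct), 100 * (2 * 0.64 - 1))
  expect_equal(unique(cyc$single_support_pct), 100 * (1 - 0.64))
  # identity: single support + total double support = stance
  expect_equal(cyc$single_support_pct + cyc$double_support_pct,
               cyc$stance_pct)
})

test_that("asymmetry splits left/right step lengths at constant mean", {
  sim <- generate_walk(walker_spec(asymmetry = 1.25))
  cyc <- sim$truth$cycles
  l <- unique(cyc$step_length_m[cyc$side == "left"])
  r <- unique(cyc$step_length_m[cyc$side == "right"])
  expect_equal(l / r, 1.25)
  expect_equal((l + r) / 2, 0.60)
})

test_that("noise and dropout are reproducible under a fixed seed", {
  a <- generate_walk(walker_spec(noise_sd_m = 0.003, dropout_rate = 0.05,
                                 seed = 42))
  b <- generate_walk(walker_spec(noise_sd_m = 0.003, dropout_rate = 0.05,
                                 seed = 42))
  expect_identical(a$markers$positions, b$markers$positions)
  c <- generate_walk(walker_spec(noise_sd_m = 0.003, dropout_rate = 0.05,
                                 seed = 43))
  expect_false(identical(a$markers$positions, c$markers$positions))
})

test_that("walkway too short for two strides is rejected", {
  expect_error(generate_walk(walker_spec(walkway_length_m = 2)),
               "walkway")
})

test_that("noise below 3 mm changes recovered step length by under 1 cm", {
  ok <- vapply(1:20, function(s) {
    sim <- generate_walk(walker_spec(noise_sd_m = 0.003, seed = s))
    rec <- compute_cycle_parameters(
      build_cycles(detect_gait_events(sim$markers)), sim$markers)
    agg <- aggregate_trial(rec)
    abs(agg$mean[agg$parameter == "step_length_m"] - 0.60) <= 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("cohort generator respects bounds, zero-SD degeneracy and seeds", {
  ct <- reference_clinical_table()
  gt <- reference_gait_table()
  sp <- cohort_spec(n_per_group = c(HS = 4, UV = 4, BV = 4), seed = 7,
                    cycles_per_subject = 5)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)
  expect_true(all(a$clinical$fga_total >= 0 & a$clinical$fga_total <= 30))
  expect_true(all(a$clinical$dhi_total >= 0 & a$clinical$dhi_total <= 100))
  expect_true(all(a$clinical$tandem_steps >= 0 & a$clinical$tandem_steps <= 11))
  expect_true(all(a$clinical$tug_s > 0))

  # zero SDs: every subject equals the group location / mean
  gt0 <- gt; gt0$sd <- 0
  ct0 <- ct; ct0$scale <- 0
  d <- generate_cohort(cohort_spec(n_per_group = c(HS = 3, UV = 3, BV = 3),
                                   gait_table = gt0, clinical_table = ct0,
                                   cycles_per_subject = 3, seed = 1))
  hs <- d$cycles[d$cycles$group == "HS" & d$cycles$speed == "slow", ]
  expect_equal(unique(hs$walking_speed_mps), 0.30)
  expect_equal(unique(d$clinical$fga_total[d$clinical$group == "BV"]), 19)

  expect_error(cohort_spec(n_per_group = c(HS = 0, UV = 3, BV = 3)),
               "positive")
})

test_that("planted group differences in speed are detected by the mixed model", {
  # comfortable-speed walking speed, reference group means, n = 10/group
  gt <- reference_gait_table()
  gt <- gt[gt$speed == "comfortable", ]
  hits <- vapply(1:100, function(s) {
    d <- generate_cohort(cohort_spec(gait_table = gt, seed = s))$cycles
    cycle_mixed_model(d, "walking_speed_mps")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
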