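test_that("noiseless events are recovered frame-for-frame by both methods", {
  sim <- default_walk() # events fall at least 0.4 frames from sample instants
  gt <- sim$truth$events
  nf <- n_frames(sim$markers)
  for (side in c("left", "right")) {
    evc <- detect_events_coordinate(sim$markers, side)
    evv <- detect_events_velocity(sim$markers, side)
    for (ev in list(evc, evv)) {
      margin <- if (ev$method[1] == "velocity") 35L else 20L
      for (kind in c("foot_strike", "foot_off")) {
        want <- interior_truth(gt[gt$side == side & gt$kind == kind, ], nf,
                               margin)
        got <- ev$frame[ev$kind == kind]
        expect_setequal(got, want$frame)
      }
    }
  }
})

test_that("noiseless detection is exact across gait-parameter combinations", {
  for (cad in c(85, 120)) {
    for (stn in c(0.58, 0.68)) {
      sim <- generate_walk(walker_spec(cadence_spm = cad,
                                       stance_fraction = stn))
      for (side in c("left", "right")) {
        ev <- detect_events_coordinate(sim$markers, side)
        errs <- event_errors(ev, sim$truth$events)
        expect_lte(max(abs(errs)), 1)
      }
    }
  }
})

test_that("3 mm marker noise leaves 95% of events within 2 frames", {
  errs <- unlist(lapply(1:20, function(s) {
    sim <- generate_walk(walker_spec(noise_sd_m = 0.003, seed = s))
    unlist(lapply(c("left", "right"), function(side) {
      event_errors(detect_events_coordinate(sim$markers, side),
                   sim$truth$events)
    }))
  }))
  expect_gte(mean(abs(errs) <= 2), 0.95)
})

test_that("methods agree within 3 frames on noiseless input", {
  sim <- default_walk()
  for (side in c("left", "right")) {
    evc <- as.data.frame(detect_events_coordinate(sim$markers, side))
    evv <- as.data.frame(detect_events_velocity(sim$markers, side))
    for (kind in c("foot_strike", "foot_off")) {
      c_f <- evc$frame[evc$kind == kind]
      v_f <- evv$frame[evv$kind == kind]
      for (f in v_f) expect_lte(min(abs(c_f - f)), 3)
    }
  }
})

test_that("degenerate trials are flagged unusable with a reason", {
  # stationary subject: no pelvis progression
  sim <- default_walk()
  ms <- sim$markers
  ms$positions <- ms$positions[rep(1L, 200), , , drop = FALSE]
  ev <- detect_events_coordinate(ms, "left")
  expect_false(attr(ev, "usable"))
  expect_match(attr(ev, "reason"), "progression")
  # zero velocity threshold: no stance detectable
  ev2 <- detect_events_velocity(sim$markers, "left", threshold_frac = 0)
  expect_false(attr(ev2, "usable"))
})

test_that("event selection prefers the cleaner method and flags violations", {
  sim <- default_walk()
  good <- combine_events(detect_events_coordinate(sim$markers, "left"),
                         detect_events_coordinate(sim$markers, "right"))
  # corrupt a copy: duplicate a strike (breaks alternation)
  bad <- good
  dup <- bad[bad$kind == "foot_strike", ][1, ]
  dup$frame <- dup$frame + 40L
  bad <- .rbind_events <- rbind(as.data.frame(bad), dup)
  attr(bad, "usable") <- TRUE
  class(bad) <- c("gait_events", class(bad))

  sel <- select_events(list(corrupt = bad, clean = good),
                       sim$markers$sample_rate)
  expect_identical(attr(sel, "selected"), "clean")

  # identical reports: the first in fixed order wins
  sel2 <- select_events(list(m1 = good, m2 = good), sim$markers$sample_rate)
  expect_identical(attr(sel2, "selected"), "m1")
  expect_equal(sel2$frame, good$frame)
  expect_equal(sel2$kind, good$kind)

  # selecting the corrupt list flags the alternation break
  sel3 <- select_events(list(only = bad), sim$markers$sample_rate)
  expect_true(any(sel3$qc_flag))

  # nothing usable: trial excluded with reasons
  un <- detect_events_velocity(sim$markers, "left", threshold_frac = 0)
  expect_error(select_events(list(velocity = un), 100), "no usable")
})

test_that("selected events are no worse than the median single-method error", {
  med_err <- function(ev, gt) median(abs(event_errors(ev, gt)))
  res <- vapply(1:50, function(s) {
    sim <- generate_walk(walker_spec(noise_sd_m = 0.002, seed = s))
    gt <- sim$truth$events
    evc <- combine_events(detect_events_coordinate(sim$markers, "left"),
                          detect_events_coordinate(sim$markers, "right"))
    evv <- combine_events(detect_events_velocity(sim$markers, "left"),
                          detect_events_velocity(sim$markers, "right"))
    sel <- select_events(list(coordinate = evc, velocity = evv),
                         sim$markers$sample_rate)
    c(sel = med_err(sel, gt), best = max(med_err(evc, gt), med_err(evv, gt)))
  }, numeric(2))
  expect_lte(median(res["sel", ]), median(res["best", ]))
})

test_that("detection is invariant to walking direction", {
  fwd <- generate_walk(walker_spec(direction = 1))
  bwd <- generate_walk(walker_spec(direction = -1))
  ef <- detect_gait_events(fwd$markers)
  eb <- detect_gait_events(bwd$markers)
  expect_equal(event_errors(eb, bwd$truth$events),
               event_errors(ef, fwd$truth$events))
})

test_that("retained events interleave strike < off < next strike per side", {
  sim <- generate_walk(walker_spec(noise_sd_m = 0.002, seed = 3))
  ev <- detect_gait_events(sim$markers)
  for (side in c("left", "right")) {
    st <- sort(ev$frame[ev$side == side & ev$kind == "foot_strike"])
    off <- sort(ev$frame[ev$side == side & ev$kind == "foot_off"])
    for (i in seq_len(length(st) - 1L)) {
      inside <- off[off > st[i] & off < st[i + 1L]]
      expect_length(inside, 1L)
    }
  }
})
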