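#' Parametric walker specification
#'
#' Defines a kinematic walking template with exactly known gait events and
#' spatiotemporal parameters, used to exercise and validate every downstream
#' stage of the pipeline against ground truth.
#'
#' The template: the pelvis (sacrum marker) advances at constant mean speed
#' with sinusoidal lateral sway; each foot is exactly stationary in the
#' horizontal plane during its stance phase and swings to the next footprint
#' with velocity = pelvis speed + a cycloidal bump (zero at toe-off and heel
#' strike). Because swing velocity never falls below pelvis speed, the
#' extrema of (heel_x - sacrum_x) and (toe_x - sacrum_x) coincide exactly
#' with the true foot strikes and foot offs, and ground contact is purely
#' geometric (heel height 0, zero horizontal velocity).
#'
#' Timing is symmetric: with stance fraction `f`, each of the two double
#' support periods lasts `f - 0.5` of the cycle, so the total double support
#' fraction is `2 f - 1` and the single support fraction is `1 - f` (the
#' contralateral swing).
#'
#' @param step_length_m mean step length (m). With `asymmetry = a`, left and
#'   right steps are `2a/(1+a)` and `2/(1+a)` times this value.
#' @param step_width_m lateral distance between left and right footprint
#'   lines (m).
#' @param cadence_spm cadence, steps per minute.
#' @param stance_fraction fraction of the gait cycle in stance, in
#'   `[0.5, 0.8)`.
#' @param leg_length_m leg length (m); sets pelvis marker height.
#' @param walkway_length_m walkway length (m), default 10.
#' @param sample_rate_hz capture frequency (Hz), default 100.
#' @param noise_sd_m isotropic Gaussian marker noise SD (m), >= 0.
#' @param dropout_rate fraction of frames per marker set to missing, in
#'   `[0, 1)`.
#' @param asymmetry left/right step-length ratio, default 1.
#' @param direction +1 walks toward +x, -1 walks back along the walkway.
#' @param heel_lift_m peak heel height during swing (m).
#' @param foot_length_m heel-to-toe marker offset (m).
#' @param seed RNG seed for noise/dropout (NULL = use current RNG state).
#' @return a list of class `walker_spec`. The derived fields
#'   `double_support_fraction` (`2*stance_fraction - 1`) and `speed_mps`
#'   (`step_length_m * cadence_spm / 60` at asymmetry 1) are included.
#' @export
walker_spec <- function(step_length_m = 0.60, step_width_m = 0.10,
                        cadence_spm = 100, stance_fraction = 0.62,
                        leg_length_m = 0.90, walkway_length_m = 10,
                        sample_rate_hz = 100, noise_sd_m = 0,
                        dropout_rate = 0, asymmetry = 1, direction = 1,
                        heel_lift_m = 0.03, foot_length_m = 0.20,
                        seed = NULL) {
  assert_scalar_num(step_length_m, "step_length_m", lower = 1e-6)
  assert_scalar_num(step_width_m, "step_width_m", lower = 0)
  assert_scalar_num(cadence_spm, "cadence_spm", lower = 1e-6)
  assert_scalar_num(stance_fraction, "stance_fraction", lower = 0.5,
                    upper = 0.8, open_upper = TRUE)
  assert_scalar_num(leg_length_m, "leg_length_m", lower = 1e-6)
  assert_scalar_num(walkway_length_m, "walkway_length_m", lower = 1e-6)
  assert_scalar_num(sample_rate_hz, "sample_rate_hz", lower = 1e-6)
  assert_scalar_num(noise_sd_m, "noise_sd_m", lower = 0)
  assert_scalar_num(dropout_rate, "dropout_rate", lower = 0, upper = 1,
                    open_upper = TRUE)
  assert_scalar_num(asymmetry, "asymmetry", lower = 1e-6)
  if (!direction %in% c(-1, 1)) stop_vg("'direction' must be +1 or -1")
  speed <- step_length_m * cadence_spm / 60
  if (speed <= 0) stop_vg("implied walking speed must be positive")
  structure(list(
    step_length_m = step_length_m, step_width_m = step_width_m,
    cadence_spm = cadence_spm, stance_fraction = stance_fraction,
    double_support_fraction = 2 * stance_fraction - 1,
    leg_length_m = leg_length_m, walkway_length_m = walkway_length_m,
    sample_rate_hz = sample_rate_hz, noise_sd_m = noise_sd_m,
    dropout_rate = dropout_rate, asymmetry = asymmetry,
    direction = direction, heel_lift_m = heel_lift_m,
    foot_length_m = foot_length_m, speed_mps = speed, seed = seed
  ), class = "walker_spec")
}

# Swing horizontal displacement profile: tau in [0,1] of swing, travel
# `stride` over duration `t_sw`, carrier velocity v plus cycloid bump.
.swing_x <- function(tau, stride, v, t_sw) {
  v * t_sw * tau + (stride - v * t_sw) * (tau - sin(2 * pi * tau) / (2 * pi))
}

# Horizontal/vertical trajectory of one foot's heel, vectorized over time t.
# Foot strikes at integer multiples of t_stride at footprints x0 + k*stride.
.foot_traj <- function(t, t_stride, stance_f, stride, x0, v, lift) {
  k <- floor(t / t_stride)
  ph <- t / t_stride - k # cycle phase in [0,1)
  x <- x0 + k * stride
  z <- numeric(length(t))
  sw <- ph > stance_f
  if (any(sw)) {
    t_sw <- (1 - stance_f) * t_stride
    tau <- (ph[sw] - stance_f) / (1 - stance_f)
    x[sw] <- x[sw] + .swing_x(tau, stride, v, t_sw)
    z[sw] <- lift * sin(pi * tau)^2
  }
  cbind(x = x, z = z)
}

#' Generate a synthetic walking trial with exact ground truth
#'
#' Produces marker trajectories (LHEE, RHEE, LTOE, RTOE, SACR) for one
#' straight pass along the walkway, plus the exact foot-strike / foot-off
#' events and per-cycle spatiotemporal parameters of the noiseless template.
#' Noise is added after the template is built; dropout after noise.
#'
#' @param spec a [walker_spec].
#' @param meta metadata list forwarded to the [marker_set].
#' @return list with elements `markers` (a [marker_set]) and `truth`, itself
#'   a list with `events` (data frame side, kind, frame, time_s), `cycles`
#'   (exact per-cycle parameter table, same columns as
#'   [compute_cycle_parameters]) and `speed_mps`.
#' @export
generate_walk <- function(spec, meta = list()) {
  stopifnot(inherits(spec, "walker_spec"))
  fs <- spec$sample_rate_hz
  t_stride <- 2 * 60 / spec$cadence_spm
  a <- spec$asymmetry
  step_l <- 2 * a / (1 + a) * spec$step_length_m # left step (L lands ahead of R by step_l)
  step_r <- 2 / (1 + a) * spec$step_length_m
  stride <- step_l + step_r
  v <- stride / t_stride
  f <- spec$stance_fraction
  w <- spec$step_width_m
  n_strides <- floor(spec$walkway_length_m / stride)
  if (n_strides < 2) stop_vg("walkway too short for two strides at this step length")

  # simulate from a quarter-cycle before the first left strike to a quarter
  # cycle after the last, so every ground-truth event is an interior sample
  t0 <- -0.25 * t_stride
  t1 <- n_strides * t_stride + 0.25 * t_stride
  nf <- floor((t1 - t0) * fs) + 1L
  t <- t0 + (seq_len(nf) - 1L) / fs

  lheel <- .foot_traj(t, t_stride, f, stride, 0, v, spec$heel_lift_m)
  rheel <- .foot_traj(t - 0.5 * t_stride, t_stride, f, stride, step_l, v,
                      spec$heel_lift_m)
  sacr_x <- v * t + (step_l - stride) / 2
  sacr_y <- 0.02 * sin(2 * pi * t / t_stride)
  sacr_z <- spec$leg_length_m + 0.015 * cos(4 * pi * t / t_stride)

  arr <- array(NA_real_, dim = c(nf, 3L, 5L),
               dimnames = list(NULL, c("x", "y", "z"),
                               c("LHEE", "RHEE", "LTOE", "RTOE", "SACR")))
  arr[, , "LHEE"] <- cbind(lheel[, "x"], w / 2, lheel[, "z"])
  arr[, , "RHEE"] <- cbind(rheel[, "x"], -w / 2, rheel[, "z"])
  arr[, , "LTOE"] <- cbind(lheel[, "x"] + spec$foot_length_m, w / 2, lheel[, "z"])
  arr[, , "RTOE"] <- cbind(rheel[, "x"] + spec$foot_length_m, -w / 2, rheel[, "z"])
  arr[, , "SACR"] <- cbind(sacr_x, sacr_y, sacr_z)

  if (spec$direction == -1) { # walk back: rotate 180 deg about vertical axis
    arr[, 1, ] <- spec$walkway_length_m - arr[, 1, ]
    arr[, 2, ] <- -arr[, 2, ]
  }

  # --- exact ground-truth events ---------------------------------------
  ks <- -2:(n_strides + 1)
  ev <- rbind(
    data.frame(side = "left", kind = "foot_strike", t_ev = ks * t_stride),
    data.frame(side = "left", kind = "foot_off", t_ev = (ks + f) * t_stride),
    data.frame(side = "right", kind = "foot_strike", t_ev = (ks + 0.5) * t_stride),
    data.frame(side = "right", kind = "foot_off", t_ev = (ks + 0.5 + f) * t_stride)
  )
  margin <- 2 / fs
  ev <- ev[ev$t_ev >= t0 + margin & ev$t_ev <= t1 - margin, ]
  ev$frame <- as.integer(round((ev$t_ev - t0) * fs)) + 1L
  ev$time_s <- (ev$frame - 1L) / fs
  ev <- ev[order(ev$frame), c("side", "kind", "frame", "time_s")]
  rownames(ev) <- NULL

  # --- exact per-cycle parameters (continuous template values) ---------
  cyc <- list()
  for (side in c("left", "right")) {
    st <- ev[ev$side == side & ev$kind == "foot_strike", "frame"]
    ncyc <- length(st) - 1L
    if (ncyc < 1) next
    sl1 <- if (side == "left") step_l else step_r # step ending the contralateral strike
    sl2 <- if (side == "left") step_r else step_l
    cyc[[side]] <- data.frame(
      side = side, cycle = seq_len(ncyc),
      step_length_m = sl1, step_width_m = w,
      cadence_spm = 120 / t_stride, walking_speed_mps = stride / t_stride,
      stance_pct = 100 * f, single_support_pct = 100 * (1 - f),
      double_support_pct = 100 * (2 * f - 1),
      stride_length_m = stride, stride_time_s = t_stride,
      step_time_s = t_stride / 2, swing_pct = 100 * (1 - f),
      stride_speed_mps = v, step_length_asymmetry = sl1 / sl2
    )
  }
  cycles <- do.call(rbind, cyc)
  rownames(cycles) <- NULL

  # --- noise then dropout ----------------------------------------------
  arr <- with_seed(spec$seed, {
    if (spec$noise_sd_m > 0) {
      arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd_m), dim = dim(arr))
    }
    if (spec$dropout_rate > 0) {
      for (m in seq_len(dim(arr)[3])) {
        drop <- runif(nf) < spec$dropout_rate
        arr[drop, , m] <- NA_real_
      }
    }
    arr
  })

  list(
    markers = marker_set(arr, fs, meta = meta),
    truth = list(events = ev, cycles = cycles, speed_mps = v,
                 stride_time_s = t_stride)
  )
}
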