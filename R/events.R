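#' Gait event detection
#'
#' Foot strikes and foot offs are detected from marker trajectories by two
#' independent methods, and the per-trial winner is chosen automatically by
#' a plausibility score ([select_events]) -- an automated stand-in for an
#' operator's visual check, with QC flags surfacing the same anomalies.
#'
#' * `detect_events_coordinate()`: foot strikes at local maxima of
#'   (heel_x - sacrum_x) and foot offs at local minima of
#'   (toe_x - sacrum_x), in the travel-aligned frame.
#' * `detect_events_velocity()`: strikes where the smoothed horizontal heel
#'   speed crosses below a threshold (default 10% of mean pelvis speed),
#'   offs where toe speed crosses back above it.
#'
#' Both use zero-phase low-pass smoothing (Butterworth, default 6 Hz, the
#' standard choice for 100 Hz gait kinematics) and enforce a minimum event
#' spacing (default 0.35 s, i.e. a cadence ceiling of ~171 steps/min).
#'
#' @param x a [marker_set] (gap-filled over the analysis span).
#' @param side `"left"` or `"right"`.
#' @param min_spacing_s minimum spacing between same-kind events (s).
#' @param cutoff_hz low-pass cutoff for pre-detection smoothing (Hz).
#' @param threshold_frac velocity threshold as a fraction of mean pelvis
#'   speed (velocity method only).
#' @return a data frame of class `gait_events` with columns
#'   `side, kind, frame, time_s, method, qc_flag`; attribute `usable`
#'   (logical) and `reason` when not usable.
#' @name gait_event_detection
NULL

# Pelvis advance per frame (m) in the travel-aligned frame; the anchor
# slope of the stance segments of (heel_x - sacrum_x) and (toe_x - sacrum_x).
.pelvis_speed_per_frame <- function(ax) {
  sac <- marker_xyz(ax, "SACR")[, 1]
  f <- seq_along(sac)
  ok <- is.finite(sac)
  unname(coef(lm(sac[ok] ~ f[ok]))[2])
}

# Refine a candidate event frame to the edge of the stance segment of y.
# During stance, y = (foot_x - sacrum_x) falls along a line of known slope
# -vpf, so lev(f) = y(f) + vpf*f is constant; the event is the first (foot
# strike, stance_side = "post") or last (foot off, stance_side = "pre")
# stance frame. For each candidate changepoint tau, the stance-side frames
# are scored by their squared deviation from their mean level and the
# swing-side frames by a one-sided envelope penalty (the foot must move
# away from the stance line by at least the pelvis advance per frame);
# the tau with the smallest total score wins. Exact for the noiseless
# stationary-stance template, and a least-squares fit under marker noise.
.refine_stance_edge <- function(y, cand, stance_side, vpf,
                                search = 8L, n_stance = 8L, n_swing = 5L) {
  n <- length(y)
  sgn <- if (stance_side == "post") 1L else -1L
  taus <- (cand - search):(cand + search)
  ok <- (taus + sgn * n_stance) >= 1 & (taus + sgn * n_stance) <= n &
    (taus - sgn * n_swing) >= 1 & (taus - sgn * n_swing) <= n
  taus <- taus[ok]
  if (!length(taus)) return(NA_integer_)
  lev <- y + vpf * (seq_len(n) - cand)
  best <- NA_integer_; best_sse <- Inf
  for (tau in rev(taus)) { # ties (event exactly between samples) -> later frame
    st <- lev[tau + sgn * (0:n_stance)]
    b <- mean(st[-1]) # level anchored away from the corner frame
    sse <- sum((st - b)^2)
    kd <- 1:n_swing
    sw_dev <- lev[tau - sgn * kd] - b
    # the true event generally falls between samples: no allowance on the
    # first swing frame (so the winning tau is the nearest frame), half a
    # frame of slack further out
    slack <- c(0, rep(0.5, n_swing - 1L))
    pen <- if (stance_side == "post") {
      pmax(0, sw_dev + abs(vpf) * (kd - slack)) # swing approach below line
    } else {
      pmax(0, abs(vpf) * (kd - slack) - sw_dev) # departing swing off line
    }
    sse <- sse + sum(pen^2)
    if (sse < best_sse - 1e-15) { best_sse <- sse; best <- tau }
  }
  best
}

.smooth_lp <- function(x, fs, cutoff_hz) {
  if (anyNA(x)) {
    stop_vg("missing samples in analysis span; run fill_gaps() first")
  }
  if (cutoff_hz >= fs / 2) return(x)
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

.side_markers <- function(side) {
  side <- match.arg(side, c("left", "right"))
  p <- if (side == "left") "L" else "R"
  list(heel = paste0(p, "HEE"), toe = paste0(p, "TOE"))
}

.events_df <- function(side, kind, frames, fs, method) {
  data.frame(side = side, kind = kind, frame = as.integer(frames),
             time_s = (as.integer(frames) - 1L) / fs, method = method,
             qc_flag = FALSE, stringsAsFactors = FALSE)
}

.unusable <- function(reason, method) {
  out <- data.frame(side = character(0), kind = character(0),
                    frame = integer(0), time_s = numeric(0),
                    method = character(0), qc_flag = logical(0))
  attr(out, "usable") <- FALSE
  attr(out, "reason") <- reason
  class(out) <- c("gait_events", class(out))
  out
}

.finish_events <- function(ev) {
  ev <- ev[order(ev$frame, ev$side, ev$kind), ]
  rownames(ev) <- NULL
  attr(ev, "usable") <- TRUE
  class(ev) <- c("gait_events", class(ev))
  ev
}

.check_progression <- function(x) {
  p <- marker_xyz(x, "SACR")
  ok <- which(complete.cases(p))
  if (length(ok) < 2) return(0)
  sqrt(sum((p[max(ok), 1:2] - p[min(ok), 1:2])^2))
}

# drop candidates too close to the trial boundary to refine (also removes
# zero-phase filter edge artifacts), then refine each to the stance edge
.clean_refine <- function(cands, y, stance_side, vpf, n, margin = 20L) {
  cands <- cands[cands > margin & cands <= n - margin]
  out <- vapply(cands, function(cc) {
    r <- .refine_stance_edge(y, cc, stance_side, vpf)
    if (is.na(r)) cc else r
  }, numeric(1))
  out <- out[out > margin & out <= n - margin]
  sort(unique(as.integer(out)))
}

#' @rdname gait_event_detection
#' @export
detect_events_coordinate <- function(x, side, min_spacing_s = 0.35,
                                     cutoff_hz = 6) {
  mk <- .side_markers(side)
  if (.check_progression(x) < 0.5) {
    return(.unusable("no pelvis progression", "coordinate"))
  }
  ax <- align_travel(x)
  fs <- x$sample_rate
  n <- n_frames(x)
  spacing <- max(1L, round(min_spacing_s * fs))
  vpf <- .pelvis_speed_per_frame(ax)
  sac <- marker_xyz(ax, "SACR")[, 1]
  d_heel <- marker_xyz(ax, mk$heel)[, 1] - sac
  d_toe <- marker_xyz(ax, mk$toe)[, 1] - sac
  strikes <- find_peaks(.smooth_lp(d_heel, fs, cutoff_hz), spacing)
  offs <- find_troughs(.smooth_lp(d_toe, fs, cutoff_hz), spacing)
  strikes <- .clean_refine(strikes, d_heel, "post", vpf, n)
  offs <- .clean_refine(offs, d_toe, "pre", vpf, n)
  if (length(strikes) < 2) {
    return(.unusable("fewer than 2 foot strikes detected", "coordinate"))
  }
  .finish_events(rbind(
    .events_df(side, "foot_strike", strikes, fs, "coordinate"),
    .events_df(side, "foot_off", offs, fs, "coordinate")
  ))
}

#' @rdname gait_event_detection
#' @export
detect_events_velocity <- function(x, side, threshold_frac = 0.10,
                                   min_spacing_s = 0.35, cutoff_hz = 6) {
  mk <- .side_markers(side)
  prog <- .check_progression(x)
  if (prog < 0.5) return(.unusable("no pelvis progression", "velocity"))
  ax <- align_travel(x)
  fs <- x$sample_rate
  spacing <- max(1L, round(min_spacing_s * fs))
  dur <- (n_frames(x) - 1) / fs
  thr <- threshold_frac * prog / dur
  if (thr <= 0) return(.unusable("non-positive velocity threshold", "velocity"))

  n <- n_frames(x)
  hspeed <- function(label) {
    m <- ax$positions[, 1:2, label]
    m[, 1] <- .smooth_lp(m[, 1], fs, cutoff_hz)
    m[, 2] <- .smooth_lp(m[, 2], fs, cutoff_hz)
    vel <- diff(m) * fs
    sp <- sqrt(rowSums(vel^2))
    c(sp[1], sp) # pad to frame count
  }
  below_h <- hspeed(mk$heel) < thr
  below_t <- hspeed(mk$toe) < thr
  if (!any(below_h) || !any(below_t)) {
    return(.unusable("no stance phase detected", "velocity"))
  }
  # candidate strike: start of a below-threshold heel run; candidate off:
  # end of a below-threshold toe run; runs shorter than a plausible stance
  # (0.15 s) are noise blips, not stances; both refined to the stance edge
  min_run <- max(2L, round(0.15 * fs))
  run_edges <- function(below, edge) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (edge == "start") starts[keep] else ends[keep]
  }
  strikes <- run_edges(below_h, "start")
  offs <- run_edges(below_t, "end")
  keep_spaced <- function(idx) idx[c(TRUE, diff(idx) >= spacing)]
  strikes <- keep_spaced(strikes)
  offs <- keep_spaced(offs)
  vpf <- .pelvis_speed_per_frame(ax)
  sac <- marker_xyz(ax, "SACR")[, 1]
  # wider margin than the coordinate method: speed is a differentiated
  # signal, so the zero-phase filter's edge transients reach further in
  strikes <- .clean_refine(strikes, marker_xyz(ax, mk$heel)[, 1] - sac,
                           "post", vpf, n, margin = 35L)
  offs <- .clean_refine(offs, marker_xyz(ax, mk$toe)[, 1] - sac,
                        "pre", vpf, n, margin = 35L)
  if (length(strikes) < 2) {
    return(.unusable("fewer than 2 foot strikes detected", "velocity"))
  }
  .finish_events(rbind(
    .events_df(side, "foot_strike", strikes, fs, "velocity"),
    .events_df(side, "foot_off", offs, fs, "velocity")
  ))
}

# Plausibility score of a combined (both-side) event list:
# (i) strict L/R alternation of strikes, (ii) low stride-time CV,
# (iii) stance fraction within [55, 75] %GC.
.plausibility <- function(ev, fs, weights = c(1, 1, 1)) {
  st <- ev[ev$kind == "foot_strike", ]
  st <- st[order(st$frame), ]
  if (nrow(st) < 3) return(-Inf)
  alt <- mean(st$side[-1] != st$side[-nrow(st)])
  cvs <- vapply(c("left", "right"), function(s) {
    f <- st$frame[st$side == s]
    if (length(f) < 3) return(NA_real_)
    d <- diff(f)
    sd(d) / mean(d)
  }, numeric(1))
  cv <- mean(cvs, na.rm = TRUE)
  s_cv <- if (is.nan(cv)) 0 else max(0, 1 - 5 * cv)
  stance_ok <- c()
  for (s in c("left", "right")) {
    fst <- sort(st$frame[st$side == s])
    fof <- sort(ev$frame[ev$side == s & ev$kind == "foot_off"])
    if (length(fst) < 2) next
    for (i in seq_len(length(fst) - 1L)) {
      o <- fof[fof > fst[i] & fof < fst[i + 1L]]
      if (length(o) == 1L) {
        stance_ok <- c(stance_ok,
                       (o - fst[i]) / (fst[i + 1L] - fst[i]) * 100)
      }
    }
  }
  s_stance <- if (length(stance_ok)) {
    mean(stance_ok >= 55 & stance_ok <= 75)
  } else 0
  sum(weights * c(alt, s_cv, s_stance))
}

#' Select the most plausible event list among detection methods
#'
#' Emulates per-trial self-selection among candidate detectors: each
#' method's combined (left + right) event list is scored by a weighted sum
#' of (i) strict left/right alternation of foot strikes, (ii) low
#' coefficient of variation of stride times and (iii) stance fraction within
#' 55-75 %GC; the highest score wins, ties broken by the fixed order of
#' `reports`. Strikes violating alternation in the winning list are
#' QC-flagged.
#'
#' @param reports named list of `gait_events` data frames (one per method,
#'   both sides combined; see [combine_events]).
#' @param sample_rate capture rate (Hz).
#' @param weights length-3 weights of the score components.
#' @return the selected `gait_events` data frame; attributes `selected`
#'   (method name) and `scores` (named numeric).
#' @export
select_events <- function(reports, sample_rate, weights = c(1, 1, 1)) {
  stopifnot(is.list(reports), length(reports) >= 1)
  usable <- vapply(reports, function(r) isTRUE(attr(r, "usable")),
                   logical(1))
  if (!any(usable)) {
    reasons <- vapply(reports, function(r) attr(r, "reason") %||% "unusable",
                      character(1))
    stop_vg("no usable event-detection method: ",
            paste(names(reports), reasons, sep = "=", collapse = "; "))
  }
  scores <- vapply(reports, function(r) {
    if (!isTRUE(attr(r, "usable"))) return(-Inf)
    .plausibility(r, sample_rate, weights)
  }, numeric(1))
  best <- which(scores == max(scores))[1] # ties: first in fixed order
  ev <- reports[[best]]
  # QC-flag strikes that break left/right alternation
  st_idx <- which(ev$kind == "foot_strike")
  st_idx <- st_idx[order(ev$frame[st_idx])]
  if (length(st_idx) > 1) {
    same <- ev$side[st_idx[-1]] == ev$side[st_idx[-length(st_idx)]]
    ev$qc_flag[st_idx[-1][same]] <- TRUE
  }
  attr(ev, "selected") <- names(reports)[best]
  attr(ev, "scores") <- scores
  ev
}

#' Combine per-side event lists of one method
#'
#' @param left,right `gait_events` for each side (same method).
#' @return combined `gait_events`; unusable if either side is unusable.
#' @export
combine_events <- function(left, right) {
  if (!isTRUE(attr(left, "usable"))) return(left)
  if (!isTRUE(attr(right, "usable"))) return(right)
  .finish_events(rbind(as.data.frame(left), as.data.frame(right)))
}

#' Detect gait events with method self-selection
#'
#' Runs all detection methods on both sides, combines and scores them, and
#' returns the selected event list.
#'
#' @inheritParams gait_event_detection
#' @param methods character vector of detector names, fixed preference
#'   order.
#' @param ... passed to the individual detectors.
#' @return as [select_events].
#' @export
detect_gait_events <- function(x, methods = c("coordinate", "velocity"),
                               ...) {
  fns <- list(coordinate = detect_events_coordinate,
              velocity = detect_events_velocity)
  methods <- match.arg(methods, names(fns), several.ok = TRUE)
  reports <- lapply(methods, function(m) {
    combine_events(fns[[m]](x, "left", ...), fns[[m]](x, "right", ...))
  })
  names(reports) <- methods
  select_events(reports, x$sample_rate)
}
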