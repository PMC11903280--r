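#' Segment gait cycles from an event list
#'
#' A gait cycle runs from one foot strike to the next strike of the same
#' foot and must contain, strictly inside, the contralateral foot off, the
#' contralateral foot strike and the ipsilateral foot off (in that order).
#' Cycles missing interior events, with non-increasing event frames, or
#' overlapping an exclusion window (e.g. the turn at a walkway end) are kept
#' but marked invalid with a machine-readable reason.
#'
#' @param events a `gait_events` data frame (both sides).
#' @param exclude_windows optional 2-column matrix / data frame of frame
#'   ranges (start, end); cycles overlapping any range are invalidated.
#' @return data frame of class `gait_cycles`: one row per cycle with the
#'   five event frames (`start, c_off, c_strike, i_off, end`), `side`,
#'   `valid`, `reason`.
#' @export
build_cycles <- function(events, exclude_windows = NULL) {
  cols <- c("side", "start", "c_off", "c_strike", "i_off", "end",
            "valid", "reason")
  empty <- data.frame(side = character(0), start = integer(0),
                      c_off = integer(0), c_strike = integer(0),
                      i_off = integer(0), end = integer(0),
                      valid = logical(0), reason = character(0))
  if (is.null(events) || nrow(events) == 0) {
    class(empty) <- c("gait_cycles", class(empty)); return(empty)
  }
  out <- list()
  for (side in c("left", "right")) {
    other <- setdiff(c("left", "right"), side)
    st <- sort(events$frame[events$side == side & events$kind == "foot_strike"])
    if (length(st) < 2) next
    i_off <- sort(events$frame[events$side == side & events$kind == "foot_off"])
    c_off <- sort(events$frame[events$side == other & events$kind == "foot_off"])
    c_st <- sort(events$frame[events$side == other & events$kind == "foot_strike"])
    for (i in seq_len(length(st) - 1L)) {
      s0 <- st[i]; s1 <- st[i + 1L]
      pick <- function(v) { x <- v[v > s0 & v < s1]; if (length(x) == 1L) x else NA_integer_ }
      row <- data.frame(side = side, start = s0, c_off = pick(c_off),
                        c_strike = pick(c_st), i_off = pick(i_off), end = s1,
                        valid = TRUE, reason = "")
      if (anyNA(row[, c("c_off", "c_strike", "i_off")])) {
        miss <- c("c_off", "c_strike", "i_off")[is.na(unlist(row[, c("c_off", "c_strike", "i_off")]))]
        row$valid <- FALSE
        row$reason <- paste0("missing interior event(s): ",
                             paste(miss, collapse = ","))
      } else if (!(s0 < row$c_off && row$c_off < row$c_strike &&
                   row$c_strike < row$i_off && row$i_off < s1)) {
        row$valid <- FALSE
        row$reason <- "events out of order"
      }
      if (row$valid && !is.null(exclude_windows)) {
        exw <- as.matrix(exclude_windows)
        hit <- any(s0 <= exw[, 2] & s1 >= exw[, 1])
        if (hit) { row$valid <- FALSE; row$reason <- "overlaps exclusion window" }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) { class(empty) <- c("gait_cycles", class(empty)); return(empty) }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$side), cols]
  rownames(res) <- NULL
  class(res) <- c("gait_cycles", class(res))
  res
}

# the 13 spatiotemporal parameters, with their dimensional role
st_parameters <- c(
  step_length_m = "length", step_width_m = "length",
  cadence_spm = "cadence", walking_speed_mps = "speed",
  stance_pct = "percent", single_support_pct = "percent",
  double_support_pct = "percent",
  stride_length_m = "length", stride_time_s = "time",
  step_time_s = "time", swing_pct = "percent",
  stride_speed_mps = "speed", step_length_asymmetry = "ratio"
)

#' Per-cycle spatiotemporal parameters
#'
#' Computes the 13 spatiotemporal parameters for each valid cycle from heel
#' ("footprint") positions at the event frames, in the travel-aligned frame.
#' A footprint is the heel-marker horizontal position at the foot-strike
#' frame. Definitions (cycle of side S, events start < c_off < c_strike <
#' i_off < end, stride = end - start frames):
#' * step length: |heel_x(c_strike, contralateral) - heel_x(start, S)|
#' * step width: perpendicular distance from the contralateral footprint to
#'   the line of progression through this cycle's initial and terminal
#'   ipsilateral footprints
#' * cadence: 120 / stride time (steps/min); walking speed: stride length /
#'   stride time
#' * stance % = (i_off - start)/stride, single support % =
#'   (c_strike - c_off)/stride, double support % =
#'   [(c_off - start) + (i_off - c_strike)]/stride, swing = 100 - stance
#' * stride length: |heel_x(end, S) - heel_x(start, S)|; step time:
#'   (c_strike - start)/fs; stride speed: pelvis displacement over the cycle
#'   divided by stride time; asymmetry: this step length over the following
#'   (contralateral-to-terminal) step length.
#'
#' @param cycles a `gait_cycles` data frame from [build_cycles].
#' @param x the [marker_set] the events came from.
#' @return data frame `st_record`: side, cycle, the 13 parameters, valid,
#'   reason. Cycles with a degenerate line of progression are invalidated.
#' @export
compute_cycle_parameters <- function(cycles, x) {
  stopifnot(inherits(x, "marker_set"))
  ax <- align_travel(x)
  fs <- x$sample_rate
  heel <- list(left = marker_xyz(ax, "LHEE"), right = marker_xyz(ax, "RHEE"))
  sacr <- marker_xyz(ax, "SACR")
  out <- list()
  counter <- c(left = 0L, right = 0L)
  for (i in seq_len(nrow(cycles))) {
    cy <- cycles[i, ]
    side <- cy$side
    counter[side] <- counter[side] + 1L
    base <- data.frame(side = side, cycle = counter[[side]])
    if (!cy$valid) {
      rec <- cbind(base, as.data.frame(as.list(setNames(
        rep(NA_real_, length(st_parameters)), names(st_parameters)))),
        valid = FALSE, reason = cy$reason)
      out[[i]] <- rec
      next
    }
    other <- setdiff(c("left", "right"), side)
    h0 <- heel[[side]][cy$start, 1:2] # initial ipsilateral footprint
    h1 <- heel[[side]][cy$end, 1:2] # terminal ipsilateral footprint
    hc <- heel[[other]][cy$c_strike, 1:2] # contralateral footprint
    stride_fr <- cy$end - cy$start
    stride_t <- stride_fr / fs
    dirv <- h1 - h0
    prog_len <- sqrt(sum(dirv^2))
    if (!all(is.finite(c(h0, h1, hc))) || prog_len < 1e-6) {
      rec <- cbind(base, as.data.frame(as.list(setNames(
        rep(NA_real_, length(st_parameters)), names(st_parameters)))),
        valid = FALSE,
        reason = if (prog_len < 1e-6) "degenerate line of progression"
                 else "missing heel position at event frame")
      out[[i]] <- rec
      next
    }
    u <- dirv / prog_len
    step_len <- abs(hc[1] - h0[1]) # along travel axis
    step_len2 <- abs(h1[1] - hc[1])
    # perpendicular distance from contralateral heel to ipsilateral line
    wvec <- hc - h0
    step_wid <- abs(-u[2] * wvec[1] + u[1] * wvec[2])
    stance <- (cy$i_off - cy$start) / stride_fr * 100
    single <- (cy$c_strike - cy$c_off) / stride_fr * 100
    double <- ((cy$c_off - cy$start) + (cy$i_off - cy$c_strike)) /
      stride_fr * 100
    sacr_disp <- abs(sacr[cy$end, 1] - sacr[cy$start, 1])
    rec <- cbind(base, data.frame(
      step_length_m = step_len, step_width_m = step_wid,
      cadence_spm = 120 / stride_t,
      walking_speed_mps = prog_len / stride_t,
      stance_pct = stance, single_support_pct = single,
      double_support_pct = double,
      stride_length_m = prog_len, stride_time_s = stride_t,
      step_time_s = (cy$c_strike - cy$start) / fs,
      swing_pct = 100 - stance,
      stride_speed_mps = sacr_disp / stride_t,
      step_length_asymmetry = if (step_len2 > 1e-9) step_len / step_len2
                              else NA_real_
    ), valid = TRUE, reason = "")
    out[[i]] <- rec
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(data.frame(side = character(0), cycle = integer(0)),
          as.data.frame(as.list(setNames(
            numeric(0)[rep(1, 0)], names(st_parameters)))),
          valid = logical(0), reason = character(0))
  rownames(res) <- NULL
  res
}

#' Trial-level summary of per-cycle records
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of each parameter over
#' the valid cycles of one trial; SD is `NA` for a single cycle.
#'
#' @param records per-cycle parameter data frame ([compute_cycle_parameters]
#'   output, or any data frame holding the 13 parameter columns and a
#'   `valid` flag).
#' @return data frame with one row per parameter: `parameter, mean, sd, n`.
#' @export
aggregate_trial <- function(records) {
  if (!is.null(records$valid)) records <- records[records$valid, ]
  if (nrow(records) == 0) {
    stop_vg("no valid cycles in trial: trial excluded")
  }
  pars <- intersect(names(st_parameters), names(records))
  data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(records[[p]]), numeric(1)),
    sd = vapply(pars, function(p) {
      if (sum(!is.na(records[[p]])) < 2) NA_real_ else sd(records[[p]])
    }, numeric(1)),
    n = vapply(pars, function(p) sum(!is.na(records[[p]])), integer(1)),
    row.names = NULL
  )
}
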