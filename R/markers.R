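#' Marker trajectory container
#'
#' A `marker_set` stores time-indexed 3D positions (in meters) for a set of
#' labelled reflective markers captured by an optical motion-capture system.
#' Positions are held in a `frames x 3 x markers` array with axes
#' `c("x","y","z")`; missing samples are `NA` (all three coordinates).
#'
#' @param positions numeric array `frames x 3 x markers`, dimnames
#'   `(NULL, c("x","y","z"), marker labels)`.
#' @param sample_rate sampling frequency in Hz (> 0).
#' @param meta optional named list of trial metadata (subject id, speed
#'   condition in `c("slow","comfortable","fast")`, trial index, group, ...).
#' @return an object of class `marker_set`.
#' @export
marker_set <- function(positions, sample_rate, meta = list()) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[2] == 3L)
  assert_scalar_num(sample_rate, "sample_rate", lower = 1e-9)
  if (is.null(dimnames(positions)[[3]])) {
    stop_vg("marker labels required as third dimnames of 'positions'")
  }
  dimnames(positions)[[2]] <- c("x", "y", "z")
  bad <- is.infinite(positions)
  if (any(bad)) stop_vg("non-finite (infinite) coordinates present")
  structure(
    list(positions = positions, sample_rate = sample_rate, meta = meta),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  d <- dim(x$positions)
  miss <- mean(is.na(x$positions[, 1, , drop = FALSE]))
  cat(sprintf(
    "<marker_set> %d frames @ %g Hz, %d markers (%s), %.1f%% missing\n",
    d[1], x$sample_rate, d[3],
    paste(utils::head(dimnames(x$positions)[[3]], 6), collapse = ","),
    100 * miss
  ))
  invisible(x)
}

#' @export
#' @rdname marker_set
#' @param x a `marker_set`.
n_frames <- function(x) dim(x$positions)[1]

#' @rdname marker_set
#' @export
marker_labels <- function(x) dimnames(x$positions)[[3]]

#' Extract one marker's trajectory
#'
#' @param x a `marker_set`.
#' @param label marker label, e.g. `"LHEE"`.
#' @return numeric `frames x 3` matrix (columns x, y, z), meters.
#' @export
marker_xyz <- function(x, label) {
  if (!label %in% marker_labels(x)) {
    stop_vg(sprintf("marker '%s' not present", label))
  }
  x$positions[, , label, drop = TRUE]
}

# Markers whose absence makes the downstream event/parameter stages
# impossible: heels, toes and a pelvis (sacrum) marker.
required_markers_default <- c("LHEE", "RHEE", "LTOE", "RTOE", "SACR")

#' Write a trial to the plain-text trajectory dialect
#'
#' Long CSV with columns `frame, marker, x_m, y_m, z_m`; missing samples are
#' written as empty fields. Frames are 1-based.
#'
#' @param x a `marker_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(x, path) {
  labs <- marker_labels(x)
  nf <- n_frames(x)
  df <- do.call(rbind, lapply(labs, function(l) {
    m <- marker_xyz(x, l)
    data.frame(frame = seq_len(nf), marker = l,
               x_m = m[, 1], y_m = m[, 2], z_m = m[, 3])
  }))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a marker-trajectory trial
#'
#' Reads the documented CSV dialect (`frame, marker, x_m, y_m, z_m`, empty
#' fields = missing) and validates that the markers required for gait-event
#' detection are present. Coordinates are converted to meters; data recorded
#' in millimeters can be read with `units = "mm"`.
#'
#' @param path file path.
#' @param format input format; only `"csv"` (the documented dialect) is
#'   supported.
#' @param sample_rate sampling frequency in Hz of the recording (the dialect
#'   does not embed it); default 100.
#' @param units `"m"` (default) or `"mm"`; millimeter data are scaled by
#'   1/1000.
#' @param required_markers labels that must be present; an error lists any
#'   absentees.
#' @param meta optional metadata list attached to the returned object.
#' @return a [marker_set].
#' @export
read_trial <- function(path, format = c("csv"), sample_rate = 100,
                       units = c("m", "mm"),
                       required_markers = required_markers_default,
                       meta = list()) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop_vg(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need_cols <- c("frame", "marker", "x_m", "y_m", "z_m")
  if (!all(need_cols %in% names(df))) {
    stop_vg("trajectory CSV must have columns frame, marker, x_m, y_m, z_m")
  }
  labs <- unique(df$marker)
  absent <- setdiff(required_markers, labs)
  if (length(absent)) {
    stop_vg(sprintf("required marker(s) missing: %s",
                    paste(absent, collapse = ", ")))
  }
  nf <- max(df$frame)
  arr <- array(NA_real_, dim = c(nf, 3L, length(labs)),
               dimnames = list(NULL, c("x", "y", "z"), labs))
  scale <- if (units == "mm") 1e-3 else 1
  for (l in labs) {
    sub <- df[df$marker == l, ]
    arr[sub$frame, 1, l] <- sub$x_m * scale
    arr[sub$frame, 2, l] <- sub$y_m * scale
    arr[sub$frame, 3, l] <- sub$z_m * scale
  }
  # a sample is missing as a whole if any coordinate is absent
  for (l in labs) {
    bad <- !complete.cases(arr[, , l])
    if (any(bad)) arr[bad, , l] <- NA_real_
  }
  marker_set(arr, sample_rate, meta = meta)
}

#' Fill marker gaps by inter-correlation reconstruction
#'
#' Gaps up to `max_gap_frames` long are reconstructed by regressing the
#' gapped marker's coordinates on principal components of co-observed
#' markers over the frames where all are valid (markers on the same body
#' move in a strongly correlated, near-rigid fashion, so a few components
#' capture the gapped marker almost exactly). When fewer than 3 reference
#' markers are available, short gaps (<= `linear_fallback_frames`) fall back
#' to per-coordinate linear interpolation. Longer gaps are left missing and
#' reported. Observed samples are never altered.
#'
#' @param x a [marker_set].
#' @param max_gap_frames longest gap (frames) that will be reconstructed;
#'   default 50 (0.5 s at 100 Hz).
#' @param linear_fallback_frames longest gap filled by linear interpolation
#'   when the PCA route is unavailable; default 5.
#' @param n_components number of principal components used in the
#'   regression; default 12 (capped by the available dimensionality), enough
#'   to carry the swing-phase detail of a small marker set while still
#'   suppressing noise directions when many markers are present.
#' @return a [marker_set] with a `fill_report` attribute: data frame of
#'   (marker, start, length, method, filled).
#' @export
fill_gaps <- function(x, max_gap_frames = 50, linear_fallback_frames = 5,
                      n_components = 12) {
  stopifnot(inherits(x, "marker_set"))
  arr <- x$positions
  labs <- marker_labels(x)
  nf <- n_frames(x)
  valid <- !apply(is.na(arr), c(1, 3), any) # frames x markers
  report <- list()

  # precondition: enough well-observed markers to anchor reconstruction
  if (sum(colMeans(valid) >= 0.5) < 3) {
    stop_vg("fill_gaps needs at least 3 markers with >= 50% valid frames")
  }

  for (m in labs) {
    vm <- valid[, m]
    if (all(vm)) next
    if (!any(vm)) {
      report[[length(report) + 1L]] <- data.frame(
        marker = m, start = 1L, length = nf, method = "none", filled = FALSE)
      next
    }
    runs <- rle(!vm)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      gs <- starts[i]; ge <- ends[i]; glen <- ge - gs + 1L
      gap <- gs:ge
      if (glen > max_gap_frames) {
        report[[length(report) + 1L]] <- data.frame(
          marker = m, start = gs, length = glen, method = "none",
          filled = FALSE)
        next
      }
      cand <- setdiff(labs, m)
      refs <- cand[colSums(!valid[gap, cand, drop = FALSE]) == 0]
      train <- which(vm & rowSums(!valid[, refs, drop = FALSE]) == 0)
      method <- "pca"
      filled <- FALSE
      if (length(refs) >= 3 && length(train) >= 10) {
        X <- do.call(cbind, lapply(refs, function(r) arr[, , r]))
        colnames(X) <- paste0(rep(refs, each = 3), "_", c("x", "y", "z"))
        pc <- prcomp(X[train, , drop = FALSE], center = TRUE, scale. = FALSE)
        keep <- which(pc$sdev > max(pc$sdev) * 1e-8) # drop rigid-degenerate dims
        k <- min(n_components, length(keep), length(train) - 2L)
        Z <- predict(pc, X)[, keep[seq_len(k)], drop = FALSE]
        # whiten so no component is discarded as numerically collinear
        Z <- sweep(Z, 2, pc$sdev[keep[seq_len(k)]], "/")
        fit_dat <- data.frame(Z[train, , drop = FALSE])
        new_dat <- data.frame(Z[gap, , drop = FALSE])
        for (ax in 1:3) {
          fit <- lm(y ~ ., data = cbind(y = arr[train, ax, m], fit_dat))
          arr[gap, ax, m] <- predict(fit, newdata = new_dat)
        }
        filled <- TRUE
      } else if (glen <= linear_fallback_frames) {
        method <- "linear"
        ok <- which(vm)
        if (any(ok < gs) && any(ok > ge)) {
          for (ax in 1:3) {
            arr[gap, ax, m] <- approx(ok, arr[ok, ax, m], xout = gap)$y
          }
          filled <- TRUE
        } else method <- "none"
      } else method <- "none"
      report[[length(report) + 1L]] <- data.frame(
        marker = m, start = gs, length = glen, method = method,
        filled = filled)
    }
  }
  out <- marker_set(arr, x$sample_rate, x$meta)
  attr(out, "fill_report") <- if (length(report)) {
    do.call(rbind, report)
  } else {
    data.frame(marker = character(0), start = integer(0),
               length = integer(0), method = character(0),
               filled = logical(0))
  }
  out
}

#' Align a trial to its travel axis
#'
#' Rotates horizontal coordinates about the vertical axis so the pelvis
#' (sacrum) net displacement points along +x. Both directions of a
#' back-and-forth walkway thus become uniform. The rotation is proper
#' (right-handed); z is unchanged.
#'
#' @param x a [marker_set].
#' @param pelvis_marker label used to detect the travel direction.
#' @return a [marker_set]; attribute `travel_axis` holds the unit vector of
#'   the original travel direction.
#' @export
align_travel <- function(x, pelvis_marker = "SACR") {
  p <- marker_xyz(x, pelvis_marker)
  ok <- which(complete.cases(p))
  if (length(ok) < 2) stop_vg("pelvis marker has fewer than 2 valid frames")
  disp <- p[max(ok), 1:2] - p[min(ok), 1:2]
  nrm <- sqrt(sum(disp^2))
  if (nrm < 1e-6) stop_vg("no pelvis progression: cannot infer travel axis")
  u <- disp / nrm
  arr <- x$positions
  xs <- arr[, 1, ]; ys <- arr[, 2, ]
  arr[, 1, ] <- u[1] * xs + u[2] * ys
  arr[, 2, ] <- -u[2] * xs + u[1] * ys
  out <- marker_set(arr, x$sample_rate, x$meta)
  attr(out, "travel_axis") <- u
  out
}
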