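#' Anthropometry record
#'
#' @param height_m standing height (m).
#' @param body_mass_kg body mass (kg). Recorded for completeness; no
#'   spatiotemporal parameter here is mass-dependent.
#' @param leg_length_m leg length L0 (m), the normalization length.
#' @param knee_width_m,ankle_width_m joint widths (m).
#' @return a list of class `anthropometry`.
#' @export
anthropometry <- function(height_m, body_mass_kg, leg_length_m,
                          knee_width_m = 0.10, ankle_width_m = 0.07) {
  for (nm in c("height_m", "body_mass_kg", "leg_length_m", "knee_width_m",
               "ankle_width_m")) {
    assert_scalar_num(get(nm), nm, lower = 1e-9)
  }
  if (leg_length_m >= height_m) stop_vg("leg_length_m must be < height_m")
  structure(list(height_m = height_m, body_mass_kg = body_mass_kg,
                 leg_length_m = leg_length_m, knee_width_m = knee_width_m,
                 ankle_width_m = ankle_width_m), class = "anthropometry")
}

# scaling divisor for one parameter role given L0 and g
.dimless_scale <- function(role, L0, g) {
  switch(role,
    length = L0,
    time = sqrt(L0 / g),
    speed = sqrt(g * L0),
    cadence = 1 / sqrt(L0 / g), # steps/min multiplied by sqrt(L0/g)
    percent = 1,
    ratio = 1,
    stop_vg("unknown parameter role: ", role)
  )
}

#' Dimensionless (leg-length / gravity) normalization
#'
#' Removes stature effects from spatiotemporal parameters by scaling:
#' lengths by `L0`, times by `sqrt(L0/g)`, speeds by `sqrt(g*L0)`, and
#' cadence (steps/min) multiplied by `sqrt(L0/g)` (the convention that keeps
#' the identity speed = step length x cadence / 60 valid in dimensionless
#' form). Percentages of the gait cycle and ratios are unchanged.
#'
#' @param records per-cycle parameter data frame (any subset of the 13
#'   parameter columns; other columns pass through unchanged).
#' @param anthro an [anthropometry], or a single positive leg length (m).
#' @param g gravitational acceleration (m/s^2), default 9.81.
#' @return the records with parameter columns scaled; attributes `L0`, `g`
#'   and class `dimensionless_record`.
#' @export
to_dimensionless <- function(records, anthro, g = 9.81) {
  L0 <- if (inherits(anthro, "anthropometry")) anthro$leg_length_m
        else anthro
  assert_scalar_num(L0, "leg_length_m (L0)", lower = 1e-12)
  assert_scalar_num(g, "g", lower = 1e-12)
  if (inherits(records, "dimensionless_record")) {
    stop_vg("records are already dimensionless")
  }
  for (p in intersect(names(st_parameters), names(records))) {
    records[[p]] <- records[[p]] / .dimless_scale(st_parameters[[p]], L0, g)
  }
  attr(records, "L0") <- L0
  attr(records, "g") <- g
  class(records) <- c("dimensionless_record", class(records))
  records
}

#' @rdname to_dimensionless
#' @param d a `dimensionless_record` produced by [to_dimensionless].
#' @return `from_dimensionless`: the SI-unit records (exact inverse).
#' @export
from_dimensionless <- function(d) {
  L0 <- attr(d, "L0"); g <- attr(d, "g")
  if (is.null(L0) || is.null(g)) {
    stop_vg("missing L0/g: not a dimensionless_record")
  }
  for (p in intersect(names(st_parameters), names(d))) {
    d[[p]] <- d[[p]] * .dimless_scale(st_parameters[[p]], L0, g)
  }
  attr(d, "L0") <- NULL
  attr(d, "g") <- NULL
  class(d) <- setdiff(class(d), "dimensionless_record")
  d
}
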