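#' Reference group-level dimensionless gait parameters
#'
#' Mean and SD of the seven canonical dimensionless spatiotemporal
#' parameters per group (HS healthy, UV unilateral, BV bilateral
#' vestibulopathy) and self-selected speed condition, from a published
#' overground-walking vestibulopathy cohort (n = 10 per group). These are
#' the default planted group structure of [generate_cohort].
#'
#' @return data frame `speed, parameter, group, mean, sd`.
#' @export
reference_gait_table <- function() {
  # columns: HS, UV, BV (mean then sd)
  row <- function(speed, par, m, s) {
    data.frame(speed = speed, parameter = par,
               group = c("HS", "UV", "BV"), mean = m, sd = s)
  }
  rbind(
    row("slow", "walking_speed_mps", c(0.30, 0.25, 0.26), c(0.04, 0.04, 0.04)),
    row("slow", "cadence_spm", c(28.03, 26.83, 28.57), c(3.41, 4.05, 2.78)),
    row("slow", "step_length_m", c(0.64, 0.56, 0.56), c(0.05, 0.08, 0.10)),
    row("slow", "step_width_m", c(0.07, 0.11, 0.12), c(0.04, 0.05, 0.05)),
    row("slow", "stance_pct", c(63.50, 66.89, 65.10), c(2.60, 2.78, 2.87)),
    row("slow", "double_support_pct", c(27.58, 33.25, 30.53), c(4.15, 4.57, 4.64)),
    row("slow", "single_support_pct", c(35.65, 33.65, 34.57), c(2.18, 2.83, 3.05)),
    row("comfortable", "walking_speed_mps", c(0.43, 0.35, 0.36), c(0.04, 0.06, 0.08)),
    row("comfortable", "cadence_spm", c(34.89, 32.41, 34.12), c(1.62, 2.37, 2.94)),
    row("comfortable", "step_length_m", c(0.75, 0.64, 0.63), c(0.06, 0.13, 0.12)),
    row("comfortable", "step_width_m", c(0.09, 0.11, 0.11), c(0.04, 0.06, 0.06)),
    row("comfortable", "stance_pct", c(61.43, 63.65, 62.91), c(1.79, 2.66, 2.35)),
    row("comfortable", "double_support_pct", c(23.66, 27.50, 25.46), c(3.25, 4.58, 4.47)),
    row("comfortable", "single_support_pct", c(37.79, 36.14, 37.45), c(1.94, 2.85, 3.24)),
    row("fast", "walking_speed_mps", c(0.60, 0.54, 0.51), c(0.05, 0.05, 0.09)),
    row("fast", "cadence_spm", c(41.53, 40.73, 41.48), c(2.31, 4.64, 3.55)),
    row("fast", "step_length_m", c(0.86, 0.80, 0.74), c(0.08, 0.12, 0.10)),
    row("fast", "step_width_m", c(0.10, 0.11, 0.12), c(0.05, 0.05, 0.05)),
    row("fast", "stance_pct", c(59.99, 60.31, 60.74), c(1.50, 2.06, 2.83)),
    row("fast", "double_support_pct", c(20.34, 21.66, 21.49), c(2.63, 3.48, 5.23)),
    row("fast", "single_support_pct", c(39.53, 38.64, 39.25), c(1.68, 1.97, 3.10))
  )
}

#' Reference group-level clinical score distributions
#'
#' Location/scale/bounds used by [generate_cohort] to draw clinical scores
#' with the group structure of the same published cohort: location = the
#' printed group median, scale = (max - min) / 4 from the printed ranges
#' (DHI uses the group mean and SD of the printed per-patient totals;
#' healthy subjects have DHI 0 by definition).
#'
#' @return data frame `measure, group, location, scale, lower, upper,
#'   rounding`.
#' @export
reference_clinical_table <- function() {
  row <- function(measure, loc, sc, lower, upper, rounding) {
    data.frame(measure = measure, group = c("HS", "UV", "BV"),
               location = loc, scale = sc, lower = lower, upper = upper,
               rounding = rounding)
  }
  dhi <- example_dhi_cohort()
  dhi_uv <- dhi$dhi_total[dhi$group == "UV"]
  dhi_bv <- dhi$dhi_total[dhi$group == "BV"]
  rbind(
    row("fga_total", c(29, 27.5, 19), c(0.75, 5.5, 3.5), 0, 30, "integer"),
    row("tug_s", c(9, 10, 10), c(0.75, 1.75, 1.5), 0.1, Inf, "none"),
    row("tandem_steps", c(10, 10, 0.75), c(1.75, 2, 0.75), 0, 11, "half"),
    row("dhi_total",
        c(0, mean(dhi_uv), mean(dhi_bv, na.rm = TRUE)),
        c(0, sd(dhi_uv), sd(dhi_bv, na.rm = TRUE)), 0, 100, "integer")
  )
}

#' Cohort simulation specification
#'
#' @param n_per_group named integer vector of group sizes (HS, UV, BV).
#' @param gait_table per-group/speed/parameter means and SDs, as
#'   [reference_gait_table].
#' @param clinical_table clinical score distributions, as
#'   [reference_clinical_table].
#' @param cycles_per_subject valid gait cycles drawn per subject and speed
#'   condition.
#' @param icc fraction of each parameter's total variance placed between
#'   subjects (the subject random intercept); the rest is cycle-to-cycle.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(HS = 10, UV = 10, BV = 10),
                        gait_table = reference_gait_table(),
                        clinical_table = reference_clinical_table(),
                        cycles_per_subject = 20, icc = 0.6, seed = NULL) {
  if (any(n_per_group <= 0)) stop_vg("group sizes must be positive")
  if (is.null(names(n_per_group))) stop_vg("n_per_group must be named")
  stopifnot(all(gait_table$sd >= 0), all(clinical_table$scale >= 0))
  assert_scalar_num(cycles_per_subject, "cycles_per_subject", lower = 1)
  assert_scalar_num(icc, "icc", lower = 0, upper = 1)
  structure(list(n_per_group = n_per_group, gait_table = gait_table,
                 clinical_table = clinical_table,
                 cycles_per_subject = cycles_per_subject, icc = icc,
                 seed = seed), class = "cohort_spec")
}

.round_score <- function(x, rounding) {
  switch(rounding,
         integer = round(x),
         half = round(x * 2) / 2,
         none = x,
         x)
}

#' Generate a synthetic cohort with planted group structure
#'
#' Draws per-cycle dimensionless gait parameters and clinical scores for a
#' three-group cohort. Each subject gets a random intercept per parameter
#' (`sd = sqrt(icc) * SD`) and cycle-level noise (`sd = sqrt(1-icc) * SD`),
#' so the mixed model's participant random effect is identifiable. Clinical
#' scores are drawn from truncated normal distributions (by resampling the
#' tails back to the bounds) and rounded to the scale's resolution; with
#' zero scale every subject equals the group location.
#'
#' @param spec a [cohort_spec].
#' @return list with `cycles` (subject, group, speed, cycle, one column per
#'   parameter) and `clinical` (subject, group, fga_total, tug_s,
#'   tandem_steps, dhi_total).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- names(spec$n_per_group)
    subjects <- unlist(lapply(groups, function(g) {
      sprintf("%s%02d", g, seq_len(spec$n_per_group[[g]]))
    }))
    subj_group <- rep(groups, times = spec$n_per_group)
    gt <- spec$gait_table
    speeds <- unique(gt$speed)
    pars <- unique(gt$parameter)
    ncyc <- spec$cycles_per_subject
    cyc <- list()
    for (si in seq_along(subjects)) {
      g <- subj_group[si]
      for (sp in speeds) {
        base <- data.frame(subject = subjects[si], group = g, speed = sp,
                           cycle = seq_len(ncyc))
        for (p in pars) {
          rowp <- gt[gt$speed == sp & gt$parameter == p & gt$group == g, ]
          b <- rnorm(1, 0, sqrt(spec$icc) * rowp$sd)
          e <- rnorm(ncyc, 0, sqrt(1 - spec$icc) * rowp$sd)
          base[[p]] <- rowp$mean + b + e
        }
        cyc[[length(cyc) + 1L]] <- base
      }
    }
    cycles <- do.call(rbind, cyc)

    ct <- spec$clinical_table
    rtrunc_norm <- function(n, m, s, lo, hi) {
      if (s == 0) return(rep(m, n))
      x <- rnorm(n, m, s)
      for (it in 1:100) {
        bad <- x < lo | x > hi
        if (!any(bad)) break
        x[bad] <- rnorm(sum(bad), m, s)
      }
      pmin(pmax(x, lo), hi)
    }
    clinical <- data.frame(subject = subjects, group = subj_group)
    for (m in unique(ct$measure)) {
      vals <- numeric(length(subjects))
      for (g in groups) {
        rowm <- ct[ct$measure == m & ct$group == g, ]
        idx <- which(subj_group == g)
        v <- rtrunc_norm(length(idx), rowm$location, rowm$scale,
                         rowm$lower, rowm$upper)
        vals[idx] <- .round_score(v, rowm$rounding)
      }
      clinical[[m]] <- vals
    }
    list(cycles = cycles, clinical = clinical)
  })
}
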