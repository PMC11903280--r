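#' Build and validate a study run configuration
#'
#' Assembles the configuration of a full simulated study run: cohort
#' composition, the three self-selected speed conditions with 3 trials each
#' (the standard overground protocol), detector and cluster settings, output
#' directory and seed. Unknown keys are rejected; defaults are injected for
#' anything omitted.
#'
#' @param ... configuration overrides; see Details.
#' @details Keys and defaults: `n_per_group` (c(HS=10,UV=10,BV=10)),
#'   `speeds` (slow/comfortable/fast), `trials_per_condition` (3), `g`
#'   (9.81), `walkway_length_m` (10), `sample_rate_hz` (100), `noise_sd_m`
#'   (0), `dropout_rate` (0), `icc` (0.6), `detector_methods`
#'   (coordinate, velocity), `cluster_k_max` (5), `out_dir` (NULL = no files
#'   written), `seed` (1), `gait_table` ([reference_gait_table]),
#'   `clinical_table` ([reference_clinical_table]).
#' @return validated config list of class `gait_config`.
#' @export
gait_config <- function(...) {
  validate_config(list(...))
}

#' @rdname gait_config
#' @param config a named list of configuration values.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    n_per_group = c(HS = 10, UV = 10, BV = 10),
    speeds = c("slow", "comfortable", "fast"),
    trials_per_condition = 3,
    g = 9.81,
    walkway_length_m = 10,
    sample_rate_hz = 100,
    noise_sd_m = 0,
    dropout_rate = 0,
    icc = 0.6,
    detector_methods = c("coordinate", "velocity"),
    cluster_k_max = 5,
    out_dir = NULL,
    seed = 1,
    gait_table = NULL,
    clinical_table = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_vg("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  cfg$gait_table <- cfg$gait_table %||% reference_gait_table()
  cfg$clinical_table <- cfg$clinical_table %||% reference_clinical_table()
  assert_scalar_num(cfg$g, "g", lower = 1e-9)
  assert_scalar_num(cfg$trials_per_condition, "trials_per_condition",
                    lower = 1)
  assert_scalar_num(cfg$sample_rate_hz, "sample_rate_hz", lower = 1)
  assert_scalar_num(cfg$noise_sd_m, "noise_sd_m", lower = 0)
  assert_scalar_num(cfg$dropout_rate, "dropout_rate", lower = 0, upper = 1,
                    open_upper = TRUE)
  if (any(cfg$n_per_group <= 0)) stop_vg("group sizes must be positive")
  bad_speed <- setdiff(cfg$speeds, c("slow", "comfortable", "fast"))
  if (length(bad_speed)) {
    stop_vg("unknown speed condition(s): ", paste(bad_speed, collapse = ", "))
  }
  class(cfg) <- c("gait_config", "list")
  cfg
}

# simulate one subject-condition-trial walk from dimensionless group targets
# and the subject's anthropometry / random effects, run event detection and
# parameter computation, and return dimensionless per-cycle records.
.run_trial <- function(targets, L0, g, trial, cfg, direction) {
  cadence_si <- targets$cadence_spm / sqrt(L0 / g)
  spec <- walker_spec(
    step_length_m = targets$step_length_m * L0,
    step_width_m = targets$step_width_m * L0,
    cadence_spm = cadence_si,
    stance_fraction = min(0.79, max(0.51, targets$stance_pct / 100)),
    leg_length_m = L0,
    walkway_length_m = cfg$walkway_length_m,
    sample_rate_hz = cfg$sample_rate_hz,
    noise_sd_m = cfg$noise_sd_m,
    dropout_rate = cfg$dropout_rate,
    direction = direction
  )
  sim <- generate_walk(spec)
  ms <- sim$markers
  if (cfg$dropout_rate > 0) ms <- fill_gaps(ms)
  ev <- detect_gait_events(ms, methods = cfg$detector_methods)
  cycles <- build_cycles(ev)
  rec <- compute_cycle_parameters(cycles, ms)
  rec$trial <- trial
  rec
}

#' Run a full simulated gait study
#'
#' End-to-end orchestration: simulate marker trajectories per subject,
#' condition and trial from the configured group-level dimensionless
#' targets; detect gait events (method self-selection); segment cycles;
#' compute per-cycle parameters; normalize to dimensionless form with each
#' subject's leg length; compare groups per speed stratum with the
#' mixed-model battery (FDR-adjusted); generate and compare clinical scores
#' (Kruskal-Wallis + Dunn); and cluster patients on (DHI, FGA). All
#' randomness is governed by `config$seed`; two runs with the same seed
#' produce identical outputs. If `config$out_dir` is set, CSV reports and an
#' exclusion log are written there.
#'
#' @param config a [gait_config].
#' @return list with `cycles_si`, `cycles_dimensionless` (per-cycle tables),
#'   `trial_summaries`, `gait_tests` (mixed-model battery), `clinical`
#'   (scores), `clinical_tests` (kw_dunn per measure), `clinical_summary`,
#'   `cluster` (twostep_cluster fit + report), `exclusions` (audit log),
#'   `config`.
#' @export
run_gait_study <- function(config = gait_config()) {
  cfg <- validate_config(unclass(config))
  with_seed(cfg$seed, {
    groups <- names(cfg$n_per_group)
    gt <- cfg$gait_table
    subj_rows <- list(); rec_rows <- list(); excl <- list()
    for (g in groups) {
      for (i in seq_len(cfg$n_per_group[[g]])) {
        sid <- sprintf("%s%02d", g, i)
        height <- rnorm(1, 1.70, 0.08)
        L0 <- 0.53 * height + rnorm(1, 0, 0.01)
        subj_rows[[sid]] <- data.frame(subject = sid, group = g,
                                       height_m = height, leg_length_m = L0)
        # subject random intercepts per parameter/speed
        for (sp in cfg$speeds) {
          tg <- gt[gt$speed == sp & gt$group == g, ]
          targets <- as.list(setNames(
            tg$mean + rnorm(nrow(tg), 0, sqrt(cfg$icc) * tg$sd),
            tg$parameter))
          for (tr in seq_len(cfg$trials_per_condition)) {
            trial_targets <- targets
            # trial-level deviation (remaining variance share)
            for (p in tg$parameter) {
              sdp <- tg$sd[tg$parameter == p]
              trial_targets[[p]] <- targets[[p]] +
                rnorm(1, 0, sqrt(1 - cfg$icc) * sdp)
            }
            direction <- if (tr %% 2 == 1) 1 else -1
            rec <- tryCatch(
              .run_trial(trial_targets, L0, cfg$g, tr, cfg, direction),
              error = function(e) e
            )
            if (inherits(rec, "error")) {
              excl[[length(excl) + 1L]] <- data.frame(
                subject = sid, group = g, speed = sp, trial = tr,
                unit = "trial", reason = conditionMessage(rec))
              next
            }
            bad <- rec[!rec$valid, , drop = FALSE]
            if (nrow(bad)) {
              excl[[length(excl) + 1L]] <- data.frame(
                subject = sid, group = g, speed = sp, trial = tr,
                unit = "cycle", reason = bad$reason)
            }
            rec <- rec[rec$valid, , drop = FALSE]
            if (nrow(rec) < 2) {
              excl[[length(excl) + 1L]] <- data.frame(
                subject = sid, group = g, speed = sp, trial = tr,
                unit = "trial", reason = "fewer than 2 valid cycles")
              next
            }
            rec$subject <- sid; rec$group <- g; rec$speed <- sp
            rec_rows[[length(rec_rows) + 1L]] <- rec
          }
        }
      }
    }
    cycles_si <- do.call(rbind, rec_rows)
    subjects <- do.call(rbind, subj_rows)
    rownames(subjects) <- NULL

    # dimensionless per subject leg length
    dl <- lapply(split(cycles_si, cycles_si$subject), function(d) {
      to_dimensionless(d, subjects$leg_length_m[subjects$subject == d$subject[1]],
                       g = cfg$g)
    })
    cycles_dl <- do.call(rbind, lapply(dl, as.data.frame))
    rownames(cycles_dl) <- NULL

    trial_summaries <- do.call(rbind, lapply(
      split(cycles_dl, list(cycles_dl$subject, cycles_dl$speed,
                            cycles_dl$trial), drop = TRUE),
      function(d) cbind(subject = d$subject[1], group = d$group[1],
                        speed = d$speed[1], trial = d$trial[1],
                        aggregate_trial(d))))
    rownames(trial_summaries) <- NULL

    gait_tests <- analyze_gait_cohort(cycles_dl)

    # clinical scores with the configured group structure
    cs <- cohort_spec(n_per_group = cfg$n_per_group,
                      gait_table = cfg$gait_table,
                      clinical_table = cfg$clinical_table,
                      icc = cfg$icc, seed = NULL)
    clinical <- generate_cohort(cs)$clinical
    measures <- setdiff(names(clinical), c("subject", "group"))
    clinical_tests <- lapply(setNames(measures, measures), function(m) {
      kw_dunn(clinical[[m]], clinical$group)
    })
    clinical_summary <- do.call(rbind, lapply(measures, function(m) {
      cbind(measure = m, group_summary(clinical[[m]], clinical$group))
    }))

    # two-step cluster on (DHI, FGA); drop cases with missing DHI
    cd <- clinical[complete.cases(clinical[, c("dhi_total", "fga_total")]), ]
    cd <- cd[order(cd$subject), ]
    cl <- twostep_cluster(cd[, c("dhi_total", "fga_total")],
                          k_max = cfg$cluster_k_max)
    cl_report <- cluster_report(cl, cd$group,
                                cd[, c("dhi_total", "fga_total")])

    exclusions <- if (length(excl)) do.call(rbind, excl) else
      data.frame(subject = character(0), group = character(0),
                 speed = character(0), trial = integer(0),
                 unit = character(0), reason = character(0))

    res <- list(cycles_si = cycles_si, cycles_dimensionless = cycles_dl,
                subjects = subjects, trial_summaries = trial_summaries,
                gait_tests = gait_tests, clinical = clinical,
                clinical_tests = clinical_tests,
                clinical_summary = clinical_summary,
                cluster = list(model = cl, report = cl_report),
                exclusions = exclusions, config = cfg)

    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(obj, name) {
        write.csv(obj, file.path(cfg$out_dir, name), row.names = FALSE)
      }
      wr(cycles_si, "cycles_si.csv")
      wr(cycles_dl, "cycles_dimensionless.csv")
      wr(trial_summaries, "trial_summaries.csv")
      wr(gait_tests$tests, "gait_tests.csv")
      if (!is.null(gait_tests$pairs)) wr(gait_tests$pairs, "gait_pairs.csv")
      wr(clinical, "clinical_scores.csv")
      wr(clinical_summary, "clinical_summary.csv")
      wr(as.data.frame(cl_report$counts), "cluster_composition.csv")
      wr(cl$bic, "cluster_bic.csv")
      wr(exclusions, "exclusion_log.csv")
    }
    res
  })
}
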