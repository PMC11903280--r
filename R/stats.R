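#' Kruskal-Wallis test with Dunn's post hoc
#'
#' Kruskal-Wallis one-way analysis of variance on ranks (tie-corrected, via
#' [stats::kruskal.test]) followed by Dunn's z-tests on rank sums for every
#' group pair. Dunn's statistic for groups i, j is
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) (1/ni + 1/nj))` with mean ranks
#' `Ri`, tie correction `T = sum(t^3 - t) / (12 (N - 1))`, and two-sided
#' normal p values. Pair p values are reported raw and BH-adjusted.
#'
#' @param values numeric outcome vector.
#' @param groups group labels aligned with `values`.
#' @return list of class `kw_dunn`: `statistic` (H), `df`, `p_value`,
#'   `pairs` (data frame pair, z, p, p_adj), `n` (per-group sizes). Groups
#'   with fewer than 2 observations are excluded with a warning.
#' @export
kw_dunn <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
    tab <- table(groups)
  }
  if (length(tab) < 2) stop_vg("kw_dunn needs at least 2 groups")
  gs <- names(tab)
  if (length(unique(values)) == 1L) { # no variation anywhere: H = 0, p = 1
    pairs <- t(utils::combn(gs, 2))
    return(structure(list(
      statistic = 0, df = length(tab) - 1L, p_value = 1,
      pairs = data.frame(pair = paste(pairs[, 1], pairs[, 2], sep = "-"),
                         z = 0, p = 1, p_adj = 1),
      n = as.integer(tab), groups = gs
    ), class = "kw_dunn"))
  }
  kw <- kruskal.test(values, factor(groups))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  T_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  pairs <- t(utils::combn(gs, 2))
  z <- p <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    se <- sqrt((N * (N + 1) / 12 - T_corr) *
               (1 / tab[[g1]] + 1 / tab[[g2]]))
    z[i] <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  structure(list(
    statistic = unname(kw$statistic), df = unname(kw$parameter),
    p_value = kw$p.value,
    pairs = data.frame(pair = paste(pairs[, 1], pairs[, 2], sep = "-"),
                       z = z, p = p, p_adj = p.adjust(p, "BH")),
    n = as.integer(tab), groups = gs
  ), class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat("Dunn post hoc (two-sided):\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' False-discovery-rate adjustment
#'
#' One-stage step-up FDR adjustment of a p-value vector. The canonical
#' one-stage procedure is Benjamini-Hochberg (default); Benjamini-Yekutieli
#' is selectable for dependent tests.
#'
#' @param p numeric vector of p values in [0, 1] (NA passed through).
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted p values, same order as input.
#' @export
fdr_adjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_vg("p values must be in [0, 1]")
  p.adjust(p, method = method)
}

#' Shapiro-Wilk normality screen
#'
#' W statistic and p value per group. Used to annotate distributions before
#' the rank-based tests, never to auto-switch tests. Groups with n < 3 or
#' zero variance are reported as not computable.
#'
#' @param values numeric vector.
#' @param groups optional group labels (default: one group).
#' @return data frame `group, n, W, p, note`.
#' @export
shapiro_screen <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(values))
  out <- lapply(unique(as.character(groups)), function(gr) {
    v <- values[groups == gr & !is.na(values)]
    if (length(v) < 3) {
      return(data.frame(group = gr, n = length(v), W = NA_real_,
                        p = NA_real_, note = "n < 3"))
    }
    if (sd(v) == 0) {
      return(data.frame(group = gr, n = length(v), W = NA_real_,
                        p = NA_real_, note = "zero variance"))
    }
    sw <- shapiro.test(v)
    data.frame(group = gr, n = length(v), W = unname(sw$statistic),
               p = sw$p.value, note = "")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mixed-model repeated-measures group comparison
#'
#' Fits a linear mixed model to per-cycle values: each valid gait cycle is a
#' unit of observation, group is a fixed effect and every participant gets a
#' random intercept (preserving within-subject correlation). The overall
#' group effect is a Satterthwaite F test; pairwise contrasts are estimated
#' marginal means (Satterthwaite degrees of freedom by default,
#' Kenward-Roger selectable). A singular random-effect fit falls back to an
#' ordinary linear model (equivalent to one-way ANOVA on cycles), flagged in
#' the output; a degenerate outcome (zero variance) yields no p value.
#'
#' @param data data frame with one row per cycle.
#' @param outcome name of the outcome column.
#' @param group_col,subject_col names of the group and participant columns.
#' @param df_method `"satterthwaite"` (default) or `"kenward-roger"`.
#' @return list of class `cycle_mm`: `p_value` (overall group F test),
#'   `F`, `df`, `pairs` (data frame pair, estimate, p), `fit`, `flag`
#'   (`""`, `"singular_fit_lm_fallback"` or `"degenerate"`), `coef_group`
#'   (fixed-effect group coefficients).
#' @export
cycle_mixed_model <- function(data, outcome, group_col = "group",
                              subject_col = "subject",
                              df_method = c("satterthwaite",
                                            "kenward-roger")) {
  df_method <- match.arg(df_method)
  d <- data.frame(
    y = data[[outcome]],
    group = factor(data[[group_col]]),
    subject = factor(data[[subject_col]])
  )
  d <- d[complete.cases(d), ]
  if (nlevels(droplevels(d$group)) < 2) stop_vg("need >= 2 groups")
  if (any(table(d$group) < 2)) stop_vg("need >= 2 observations per group")
  if (sd(d$y) < 1e-12) {
    return(structure(list(p_value = NA_real_, F = NA_real_, df = c(NA, NA),
                          pairs = NULL, fit = NULL, flag = "degenerate"),
                     class = "cycle_mm"))
  }
  flag <- ""
  fit_warnings <- character(0)
  fit <- tryCatch(
    withCallingHandlers(
      suppressMessages(lmerTest::lmer(y ~ group + (1 | subject), data = d,
                                      REML = TRUE)),
      warning = function(w) { # collect optimizer chatter into the result
        fit_warnings <<- c(fit_warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NULL
  )
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    flag <- "singular_fit_lm_fallback"
    fit_lm <- lm(y ~ group, data = d)
    an <- anova(fit_lm)
    emm <- emmeans::emmeans(fit_lm, "group")
    prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
    return(structure(list(
      p_value = an[["Pr(>F)"]][1], F = an[["F value"]][1],
      df = c(an$Df[1], an$Df[2]),
      pairs = data.frame(pair = prs$contrast, estimate = prs$estimate,
                         p = prs$p.value),
      fit = fit_lm, flag = flag,
      coef_group = coef(fit_lm)[-1]
    ), class = "cycle_mm"))
  }
  an <- anova(fit) # lmerTest: Satterthwaite type III
  lmer_df <- if (df_method == "satterthwaite") "satterthwaite" else
    "kenward-roger"
  emm <- emmeans::emmeans(fit, "group", lmer.df = lmer_df)
  prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  structure(list(
    p_value = an[["Pr(>F)"]][1], F = an[["F value"]][1],
    df = c(an$NumDF[1], an$DenDF[1]),
    pairs = data.frame(pair = prs$contrast, estimate = prs$estimate,
                       p = prs$p.value),
    fit = fit, flag = flag, fit_warnings = fit_warnings,
    coef_group = lme4::fixef(fit)[-1]
  ), class = "cycle_mm")
}

#' @export
print.cycle_mm <- function(x, ...) {
  cat(sprintf("Mixed model group effect: F(%s, %s) = %.4g, p = %.4g %s\n",
              format(x$df[1]), format(round(x$df[2], 1)), x$F, x$p_value,
              if (nzchar(x$flag)) paste0("[", x$flag, "]") else ""))
  if (!is.null(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Mixed-model battery over speeds and parameters
#'
#' Fits [cycle_mixed_model] per speed stratum and parameter, then adjusts
#' the overall p values by one-stage FDR ([fdr_adjust]) across the whole
#' family. Pairwise contrast p values are reported raw and FDR-adjusted
#' within the family of contrasts.
#'
#' @param cycles long-format data frame with columns `subject`, `group`,
#'   `speed`, and one column per parameter.
#' @param parameters parameter columns to analyse (default: the canonical
#'   seven).
#' @param speeds speed strata to analyse (default: all present).
#' @param ... passed to [cycle_mixed_model].
#' @return list with `tests` (tidy data frame speed, parameter, F, p_raw,
#'   p_adj, flag) and `pairs` (speed, parameter, pair, estimate, p_raw,
#'   p_adj).
#' @export
analyze_gait_cohort <- function(cycles,
                                parameters = c("walking_speed_mps",
                                               "cadence_spm",
                                               "step_length_m",
                                               "step_width_m", "stance_pct",
                                               "double_support_pct",
                                               "single_support_pct"),
                                speeds = NULL, ...) {
  speeds <- speeds %||% unique(as.character(cycles$speed))
  parameters <- intersect(parameters, names(cycles))
  tests <- list(); pairs <- list()
  for (sp in speeds) {
    sub <- cycles[cycles$speed == sp, ]
    for (p in parameters) {
      mm <- cycle_mixed_model(sub, p, ...)
      tests[[length(tests) + 1L]] <- data.frame(
        speed = sp, parameter = p, F = mm$F, p_raw = mm$p_value,
        flag = mm$flag)
      if (!is.null(mm$pairs)) {
        pairs[[length(pairs) + 1L]] <- cbind(
          data.frame(speed = sp, parameter = p), mm$pairs)
      }
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_adj <- fdr_adjust(tests$p_raw)
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  if (!is.null(pairs)) {
    names(pairs)[names(pairs) == "p"] <- "p_raw"
    pairs$p_adj <- fdr_adjust(pairs$p_raw)
  }
  list(tests = tests, pairs = pairs)
}
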