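#' Functional Gait Assessment total score
#'
#' The FGA battery has 10 walking tasks, each scored on a four-point ordinal
#' scale 0-3 (0 = severe impairment); the total is the item sum (max 30).
#'
#' @param items integer vector of exactly 10 item scores, each in 0..3.
#' @return integer total in 0..30.
#' @export
fga_total <- function(items) {
  if (length(items) != 10) stop_vg("FGA requires exactly 10 item scores")
  if (anyNA(items) || !is.numeric(items) || any(items != as.integer(items)) ||
      any(items < 0 | items > 3)) {
    stop_vg("FGA items must be integers in 0..3")
  }
  as.integer(sum(items))
}

#' Timed Up and Go mobility category
#'
#' Categorizes a TUG time: < 10 s normal mobility, 10-20 s good mobility,
#' > 29 s impaired mobility; times in (20, 29] fall in a band the scale does
#' not name and are reported as `"uncategorized"`. Times >= 12 s additionally
#' flag an elevated fall risk.
#'
#' @param tug_s TUG completion time in seconds (> 0); vectorized.
#' @return data frame with columns `tug_s`, `category` (factor: normal,
#'   good, uncategorized, impaired) and `fall_risk` (logical).
#' @export
tug_category <- function(tug_s) {
  if (any(!is.finite(tug_s)) || any(tug_s <= 0)) {
    stop_vg("TUG times must be positive")
  }
  cat <- ifelse(tug_s < 10, "normal",
         ifelse(tug_s <= 20, "good",
         ifelse(tug_s > 29, "impaired", "uncategorized")))
  data.frame(
    tug_s = tug_s,
    category = factor(cat, levels = c("normal", "good", "uncategorized",
                                      "impaired")),
    fall_risk = tug_s >= 12
  )
}

#' Dizziness Handicap Inventory severity band
#'
#' DHI totals (0-100): 0 none, 16-34 mild, 36-52 moderate, 54-100 severe.
#' The scale's bands are not exhaustive; totals of 1-15, 35 or 53 are
#' reported as `"unbanded"` rather than silently assigned.
#'
#' @param dhi_total DHI total in 0..100; vectorized, `NA` allowed.
#' @return factor with levels none, mild, moderate, severe, unbanded.
#' @export
dhi_band <- function(dhi_total) {
  if (any(dhi_total < 0 | dhi_total > 100, na.rm = TRUE)) {
    stop_vg("DHI totals must be in [0, 100]")
  }
  band <- ifelse(is.na(dhi_total), NA_character_,
          ifelse(dhi_total == 0, "none",
          ifelse(dhi_total >= 16 & dhi_total <= 34, "mild",
          ifelse(dhi_total >= 36 & dhi_total <= 52, "moderate",
          ifelse(dhi_total >= 54, "severe", "unbanded")))))
  factor(band, levels = c("none", "mild", "moderate", "severe", "unbanded"))
}

#' Per-group summary of a clinical score
#'
#' Median, min, max, mean and n per group, excluding missing values
#' pairwise (exclusion counts are reported). Published cohort tables of this
#' kind are usually headed "median (min-max)", but the mean is reported too
#' because some printed group entries are only reproduced by the mean (see
#' the package vignette).
#'
#' @param values numeric score vector.
#' @param groups group labels aligned with `values`.
#' @return data frame `group, n, n_missing, median, min, max, mean`; empty
#'   groups are omitted with a warning.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- lapply(unique(as.character(groups)), function(gr) {
    v <- values[groups == gr]
    nm <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning(sprintf("group '%s' has no non-missing values; omitted", gr))
      return(NULL)
    }
    data.frame(group = gr, n = length(v), n_missing = nm,
               median = median(v), min = min(v), max = max(v),
               mean = mean(v))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundled DHI example cohort
#'
#' Dizziness Handicap Inventory totals for a published clinical cohort of 10
#' chronic unilateral (UV) and 10 bilateral (BV) vestibulopathy patients
#' (one BV total missing), plus 10 healthy subjects whose DHI is 0 by
#' definition. Used as a worked example and as a reproduction fixture for
#' the group-summary arithmetic.
#'
#' @return data frame `subject, group, dhi_total`.
#' @export
example_dhi_cohort <- function() {
  bv <- c(2, 48, 48, 20, 34, 74, 40, NA, 46, 12)
  uv <- c(68, 8, 20, 11, 6, 64, 52, 2, 14, 22)
  data.frame(
    subject = c(sprintf("HS%02d", 1:10), sprintf("UV%02d", 1:10),
                sprintf("BV%02d", 1:10)),
    group = rep(c("HS", "UV", "BV"), each = 10),
    dhi_total = c(rep(0, 10), uv, bv)
  )
}
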