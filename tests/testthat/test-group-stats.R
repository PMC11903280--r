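# independent brute-force Dunn oracle: explicit rank arithmetic
dunn_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  Tc <- sum(ties^3 - ties) / (12 * (N - 1))
  gs <- sort(unique(groups))
  out <- c()
  for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
    mi <- mean(r[groups == gs[i]]); mj <- mean(r[groups == gs[j]])
    ni <- sum(groups == gs[i]); nj <- sum(groups == gs[j])
    z <- (mi - mj) / sqrt((N * (N + 1) / 12 - Tc) * (1 / ni + 1 / nj))
    out <- c(out, 2 * pnorm(-abs(z)))
  }
  out
}

test_that("Kruskal-Wallis and Dunn match brute-force rank computation", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("A", "B", "C"), each = 3)
  res <- kw_dunn(v, g)
  expect_equal(res$statistic, 7.2, tolerance = 1e-10)
  expect_equal(res$p_value, 0.02732, tolerance = 1e-3)
  expect_equal(res$pairs$p, dunn_oracle(v, g), tolerance = 1e-12)
  # tie-free random inputs, n <= 12: exact match against the oracle
  set.seed(4)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    v2 <- sample(seq_len(100), n) # tie-free
    g2 <- sample(rep(c("A", "B", "C"), length.out = n))
    if (min(table(g2)) < 2) next
    expect_equal(kw_dunn(v2, g2)$pairs$p, dunn_oracle(v2, g2),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give H = 0 and undersized groups are excluded", {
  res <- kw_dunn(rep(5, 9), rep(c("A", "B", "C"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_warning(kw_dunn(c(1, 2, 3, 4, 5), c("A", "A", "B", "B", "C")),
                 "C")
})

test_that("Kruskal-Wallis detects a 2-SD shift at n = 10 per group", {
  set.seed(11)
  hits <- replicate(200, {
    g <- rep(c("A", "B", "C"), each = 10)
    v <- rnorm(30) + (g == "C") * 2
    kw_dunn(v, g)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("FDR adjustment follows the one-stage step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_true(all(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)) <= 0.05))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  # order invariance
  p <- c(0.04, 0.001, 0.3, 0.02)
  perm <- c(3, 1, 4, 2)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
  # adjusted >= raw
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("Shapiro screen reports W per group and flags degenerate inputs", {
  sw <- shapiro_screen(c(1, 2, 3))
  expect_equal(sw$W, 1, tolerance = 1e-10) # equal-spaced quantiles
  sw2 <- shapiro_screen(c(1, 1, 1, 5), c("a", "a", "a", "b"))
  expect_equal(sw2$note, c("zero variance", "n < 3"))
  set.seed(8)
  hits <- replicate(100, {
    shapiro_screen(rt(50, df = 1))$p < 0.05 # heavy-tailed sample
  })
  expect_gte(mean(hits), 0.9)
})

test_that("mixed model recovers a planted group offset", {
  set.seed(21)
  est <- replicate(100, {
    subj <- factor(rep(1:30, each = 20))
    grp <- factor(rep(c("HS", "UV", "BV"), each = 200),
                  levels = c("HS", "UV", "BV"))
    b <- rnorm(30, 0, 1)[as.integer(subj)]
    y <- b + rnorm(600, 0, 0.5) + (grp == "BV") * 1 # offset = 1 between-SD
    d <- data.frame(y = y, group = grp, subject = subj)
    m <- cycle_mixed_model(d, "y")
    unname(m$coef_group["groupBV"])
  })
  expect_lt(abs(median(est) - 1), 0.2)
})

test_that("mixed model reduces to one-way ANOVA with one cycle per subject", {
  set.seed(5)
  d <- data.frame(
    y = rnorm(30, rep(c(0, 0.3, 0.6), each = 10)),
    group = rep(c("A", "B", "C"), each = 10),
    subject = paste0("s", 1:30)
  )
  m <- cycle_mixed_model(d, "y")
  expect_equal(m$flag, "singular_fit_lm_fallback")
  a <- anova(lm(y ~ group, data = d))
  expect_equal(m$p_value, a[["Pr(>F)"]][1], tolerance = 1e-6)
})

test_that("degenerate outcomes yield a flag and no p value", {
  d <- data.frame(y = rep(1, 40), group = rep(c("A", "B"), each = 20),
                  subject = rep(1:8, each = 5))
  m <- cycle_mixed_model(d, "y")
  expect_equal(m$flag, "degenerate")
  expect_true(is.na(m$p_value))
})

test_that("the cohort battery fits per speed and parameter with FDR", {
  d <- generate_cohort(cohort_spec(n_per_group = c(HS = 5, UV = 5, BV = 5),
                                   cycles_per_subject = 8, seed = 3))
  res <- analyze_gait_cohort(d$cycles,
                             parameters = c("walking_speed_mps",
                                            "stance_pct"),
                             speeds = c("slow", "comfortable"))
  expect_equal(nrow(res$tests), 4)
  expect_true(all(res$tests$p_adj >= res$tests$p_raw))
  expect_equal(sort(unique(as.character(res$pairs$pair))),
               sort(c("BV - HS", "BV - UV", "HS - UV")))
})
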