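test_that("Welch t matches the hand formula and its invariances", {
  a <- c(1, 2, 3); b <- c(2, 3, 4, 5)
  got <- welch_t(a, b)
  ref <- welch_by_hand(a, b)
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(got$df, ref$df, tolerance = 1e-12)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # equal n and equal variances: Welch equals the pooled Student t
  x <- c(4.1, 5.2, 6.3, 7.1); y <- x + 1.5  # same spread, shifted
  expect_equal(welch_t(x, y)$statistic,
               unname(t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-12)

  # invariance under relabeling (sign flips) and constant shift
  set.seed(2)
  g1 <- rnorm(6, 10); g2 <- rnorm(8, 12)
  expect_equal(welch_t(g1, g2)$p.value, welch_t(g2, g1)$p.value)
  expect_equal(welch_t(g1 + 100, g2 + 100)$p.value, welch_t(g1, g2)$p.value,
               tolerance = 1e-12)

  expect_error(welch_t(c(1, 1, 1), g2), "variance")
  expect_error(welch_t(1, g2), "at least 2")
})

test_that("Bonferroni adjustment is min(1, m p)", {
  expect_equal(bonferroni(c(0.01, 0.2), 1), c(0.01, 0.2))
  expect_equal(bonferroni(0.03, 2), 0.06)
  expect_equal(bonferroni(0.8, 4), 1)
  expect_equal(bonferroni(c(0.025, 0.6), 2),
               p.adjust(c(0.025, 0.6), "bonferroni"))
  expect_error(bonferroni(1.2, 2), "0, 1")
  expect_error(bonferroni(0.5, 0), "m")
})

test_that("attrition inflation takes the ceiling of n / (1 - rate)", {
  expect_identical(attrition_adjust(6, 0.30), 9L)
  expect_identical(attrition_adjust(6, 0), 6L)
  expect_identical(attrition_adjust(6, 0.5), 12L)
  expect_identical(attrition_adjust(7, 0.30), 10L)  # float-safe: not 11
  expect_error(attrition_adjust(6, 1), "attrition_rate")
  expect_error(attrition_adjust(0, 0.3), "n_required")
})

test_that("interaction F equals the squared pooled t on change scores", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)  # unbalanced allowed
    tbl <- random_cohort_table(n1, n2, effect_a = runif(1, -2, 2),
                               effect_b = runif(1, -2, 2))
    a <- mixed_anova(tbl, "x")
    wide <- reshape(tbl[, c("subject_id", "cohort", "timepoint", "value")],
                    idvar = c("subject_id", "cohort"),
                    timevar = "timepoint", direction = "wide")
    d <- wide$value.post - wide$value.baseline
    tt <- t.test(d[wide$cohort == "a"], d[wide$cohort == "b"],
                 var.equal = TRUE)
    expect_equal(a$F_interaction, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_identical(unname(a$df), c(1L, n1 + n2 - 2L))
    expect_equal(a$p_interaction, tt$p.value, tolerance = 1e-10)
  }
})

test_that("interaction F matches aov and the brute-force SS decomposition", {
  set.seed(13)
  for (i in 1:10) {
    tbl <- random_cohort_table(6, 6, effect_a = runif(1, -3, 3),
                               effect_b = runif(1, -3, 3))
    a <- mixed_anova(tbl, "x")
    expect_equal(a$F_interaction, aov_interaction_F(tbl), tolerance = 1e-8)
    expect_equal(a$F_interaction, ss_interaction_F(tbl), tolerance = 1e-8)
  }
})

test_that("identical shifts in both cohorts give no interaction", {
  ids <- sprintf("s%02d", 1:10)
  tbl <- data.frame(
    subject_id = rep(ids, 2), cohort = rep(rep(c("a", "b"), each = 5), 2),
    timepoint = rep(c("baseline", "post"), each = 10), parameter = "x",
    value = c(1:10, 1:10 + 5))  # every subject shifts by exactly +5
  expect_equal(mixed_anova(tbl, "x")$F_interaction, 0)
  expect_equal(mixed_anova(tbl, "x")$p_interaction, 1)
})

test_that("incomplete subjects are dropped with a warning", {
  tbl <- random_cohort_table(5, 5)
  tbl <- tbl[!(tbl$subject_id == "a_01" & tbl$timepoint == "post"), ]
  expect_warning(a <- mixed_anova(tbl, "x"), "incomplete")
  expect_identical(unname(a$n), c(4L, 5L))
  expect_identical(unname(a$df), c(1L, 7L))
})

test_that("post hoc paired comparisons are Bonferroni-adjusted", {
  set.seed(77)
  tbl <- random_cohort_table(6, 6, effect_a = 4, effect_b = 0)
  a <- mixed_anova(tbl, "x")
  expect_equal(a$posthoc$p_adj, pmin(1, 2 * a$posthoc$p_raw))
  expect_true(all(a$posthoc$p_adj >= a$posthoc$p_raw))
  # the raw p is the within-cohort paired t on baseline vs post
  d <- with(tbl, value[cohort == "a" & timepoint == "post"] -
              value[cohort == "a" & timepoint == "baseline"])
  expect_equal(a$posthoc$p_raw[a$posthoc$cohort == "a"], t.test(d)$p.value,
               tolerance = 1e-12)
})

test_that("cohort summaries report mean and SEM per cell", {
  tbl <- data.frame(subject_id = c("s1", "s2", "s3"), cohort = "a",
                    timepoint = "baseline", parameter = "x",
                    value = c(1, 2, 3))
  s <- summarize_cohort(tbl)
  expect_equal(s$mean, 2)
  expect_equal(s$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(round(s$sem, 3), 0.577)

  one <- tbl[1, ]
  expect_warning(s1 <- summarize_cohort(one), "single value")
  expect_equal(s1$sem, 0)

  lines <- format_cohort_summary(s)
  expect_match(lines, "x.*baseline.*n=3", all = FALSE)
})

test_that("cohort table invariants are enforced", {
  tbl <- random_cohort_table(3, 3)
  dup <- rbind(tbl, tbl[1, ])
  expect_error(summarize_cohort(dup), "duplicate")
  bad <- tbl; bad$cohort[bad$subject_id == "a_01"][1] <- "b"
  expect_error(mixed_anova(bad, "x"), "more than one cohort")
  expect_error(mixed_anova(tbl, "nope"), "not in table")
})
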