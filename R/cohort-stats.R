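#' Welch's unpaired t test
#'
#' Two-sample t test with Welch's correction for unequal variances
#' (Welch-Satterthwaite degrees of freedom), the baseline between-cohort
#' comparison of the study. Thin wrapper over [stats::t.test()] with the
#' degenerate-variance guard the downstream tables rely on.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2 with
#'   positive variance.
#' @return List with `statistic` (t), `df` and `p.value` (two-sided).
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(group_a)) || !all(is.finite(group_b))) {
    stop("groups must be finite", call. = FALSE)
  }
  if (stats::var(group_a) <= 0 || stats::var(group_b) <= 0) {
    stop("degenerate variance: each group must have positive variance",
         call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise, for a family of `m` comparisons.
#'
#' @param p_values Numeric vector of raw p values in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return Adjusted p values, same length.
#' @export
bonferroni <- function(p_values, m) {
  if (!all(is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("`p_values` must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(m, "m")
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  pmin(1, m * p_values)
}

#' Inflate a required sample size for expected attrition
#'
#' Smallest integer n with `n * (1 - rate) >= n_required`, i.e.
#' `ceiling(n_required / (1 - rate))`. With the study's 30% attrition
#' assumption, a power-calculation requirement of 6 per group becomes 9.
#'
#' @param n_required Required completers per group (integer >= 1).
#' @param attrition_rate Expected attrition fraction in `[0, 1)`.
#' @return Projected recruitment per group (integer).
#' @examples
#' attrition_adjust(6, 0.30)  # 9
#' @export
attrition_adjust <- function(n_required, attrition_rate) {
  n_required <- as.integer(n_required)
  if (is.na(n_required) || n_required < 1L) {
    stop("`n_required` must be an integer >= 1", call. = FALSE)
  }
  stop_if_not_scalar_number(attrition_rate, "attrition_rate")
  if (attrition_rate < 0 || attrition_rate >= 1) {
    stop("`attrition_rate` must lie in [0, 1)", call. = FALSE)
  }
  # tolerance guards float artefacts like 7/0.7 = 10.000000000000002
  as.integer(ceiling(n_required / (1 - attrition_rate) - 1e-9))
}

check_cohort_table <- function(table) {
  req <- c("subject_id", "cohort", "timepoint", "parameter", "value")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    stop("cohort table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table[c("subject_id", "timepoint", "parameter")])) {
    stop("duplicate (subject, timepoint, parameter) records", call. = FALSE)
  }
  by_subj <- unique(table[c("subject_id", "cohort")])
  if (anyDuplicated(by_subj$subject_id)) {
    stop("a subject appears in more than one cohort", call. = FALSE)
  }
  invisible(table)
}

#' Mixed-design repeated-measures two-way ANOVA (2 x 2)
#'
#' The study's intervention analysis: between factor = cohort, within
#' factor = timepoint (baseline vs post). For a 2 x 2 mixed design the
#' cohort x timepoint interaction F on `(1, n_total - 2)` degrees of
#' freedom equals the squared pooled two-sample t statistic on the
#' per-subject change scores, which is how it is computed here; the
#' change-score formulation stays exact for unbalanced cohorts. Post hoc
#' baseline-vs-post paired t tests are run within each cohort and
#' Bonferroni-adjusted for the family of 2 comparisons. Subjects missing
#' either timepoint are dropped with a warning (complete-case analysis).
#'
#' @param table Long-format cohort table (see [synthesize_cohort()]):
#'   columns `subject_id`, `cohort`, `timepoint` (`baseline` / `post`),
#'   `parameter`, `value`; exactly two cohorts, >= 2 complete subjects
#'   per cohort.
#' @param parameter Which parameter to analyse.
#' @return A `mixed_anova` list: `F_interaction`, `df` (c(between,
#'   within) = c(1, n - 2)), `p_interaction`, `posthoc` (per-cohort change
#'   mean +/- SEM, raw and Bonferroni-adjusted p), `cells` (per
#'   cohort x timepoint mean +/- SEM) and `n` per cohort.
#' @export
mixed_anova <- function(table, parameter) {
  check_cohort_table(table)
  tab <- table[table$parameter == parameter, , drop = FALSE]
  if (nrow(tab) == 0L) stop(sprintf("parameter '%s' not in table", parameter),
                            call. = FALSE)
  if (!all(c("baseline", "post") %in% tab$timepoint)) {
    stop("both 'baseline' and 'post' timepoints are required", call. = FALSE)
  }
  cohorts <- sort(unique(tab$cohort))
  if (length(cohorts) != 2L) stop("exactly two cohorts are required", call. = FALSE)

  wide <- merge(
    tab[tab$timepoint == "baseline", c("subject_id", "cohort", "value")],
    tab[tab$timepoint == "post", c("subject_id", "value")],
    by = "subject_id", suffixes = c("_baseline", "_post")
  )
  n_all <- length(unique(tab$subject_id))
  if (nrow(wide) < n_all) {
    warning(sprintf("%d incomplete subject(s) dropped for parameter '%s'",
                    n_all - nrow(wide), parameter), call. = FALSE)
  }
  wide$delta <- wide$value_post - wide$value_baseline
  d1 <- wide$delta[wide$cohort == cohorts[1]]
  d2 <- wide$delta[wide$cohort == cohorts[2]]
  n1 <- length(d1); n2 <- length(d2)
  if (n1 < 2L || n2 < 2L) {
    stop("need >= 2 complete subjects per cohort", call. = FALSE)
  }

  # pooled two-sample t on change scores; its square is the interaction F
  sp2 <- ((n1 - 1) * stats::var(d1) + (n2 - 1) * stats::var(d2)) / (n1 + n2 - 2)
  mean_gap <- mean(d1) - mean(d2)
  df <- c(between = 1L, within = n1 + n2 - 2L)
  if (sp2 == 0) {
    # degenerate: every subject shifts identically within each cohort
    F_int <- if (mean_gap == 0) 0 else Inf
  } else {
    F_int <- (mean_gap / sqrt(sp2 * (1 / n1 + 1 / n2)))^2
  }
  p_int <- stats::pf(F_int, df[1], df[2], lower.tail = FALSE)

  posthoc <- do.call(rbind, lapply(cohorts, function(g) {
    d <- wide$delta[wide$cohort == g]
    # paired baseline-vs-post == one-sample t on deltas; a zero-variance
    # cohort is degenerate (p = 1 for no change, 0 for a certain change)
    p_raw <- if (stats::sd(d) == 0) as.numeric(mean(d) == 0)
             else stats::t.test(d)$p.value
    data.frame(cohort = g, n = length(d), delta_mean = mean(d),
               delta_sem = stats::sd(d) / sqrt(length(d)),
               p_raw = p_raw, stringsAsFactors = FALSE)
  }))
  posthoc$p_adj <- bonferroni(posthoc$p_raw, m = 2)

  cells <- summarize_cohort(tab)
  structure(
    list(parameter = parameter, F_interaction = F_int, df = df,
         p_interaction = p_int, posthoc = posthoc, cells = cells,
         n = stats::setNames(c(n1, n2), cohorts)),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed-design two-way ANOVA: %s\n", x$parameter))
  cat(sprintf("  cohort x timepoint interaction: F(%d,%d) = %s, p = %s\n",
              x$df[1], x$df[2], format(x$F_interaction, digits = digits),
              format.pval(x$p_interaction, digits = digits)))
  for (i in seq_len(nrow(x$posthoc))) {
    r <- x$posthoc[i, ]
    cat(sprintf("  %s (n = %d): change %+.2f +/- %.2f, adj. p = %s\n",
                r$cohort, r$n, r$delta_mean, r$delta_sem,
                format.pval(r$p_adj, digits = digits)))
  }
  invisible(x)
}

#' Per-cell summary of a cohort table
#'
#' Mean +/- SEM per (parameter, cohort, timepoint) cell, the study's
#' reporting convention. A single-value cell has no dispersion estimate
#' and is reported with SEM 0 and a warning.
#'
#' @param table Long-format cohort table.
#' @return Data frame with columns `parameter`, `cohort`, `timepoint`,
#'   `n`, `mean`, `sem`.
#' @export
summarize_cohort <- function(table) {
  check_cohort_table(table)
  cells <- unique(table[c("parameter", "cohort", "timepoint")])
  cells <- cells[order(cells$parameter, cells$cohort, cells$timepoint), ]
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$parameter == cells$parameter[i] &
      table$cohort == cells$cohort[i] & table$timepoint == cells$timepoint[i]
    v <- table$value[sel]
    sem <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else {
      warning(sprintf("cell %s/%s/%s has a single value: SEM reported as 0",
                      cells$parameter[i], cells$cohort[i], cells$timepoint[i]),
              call. = FALSE)
      0
    }
    data.frame(cells[i, ], n = length(v), mean = mean(v), sem = sem,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Format a cohort summary as an aligned text table
#'
#' @param summary Output of [summarize_cohort()].
#' @param digits Decimal places.
#' @return Character vector of report lines (one per cell), invisibly
#'   printable via `cat(..., sep = "\n")`.
#' @export
format_cohort_summary <- function(summary, digits = 1) {
  stopifnot(is.data.frame(summary),
            all(c("parameter", "cohort", "timepoint", "n", "mean", "sem")
                %in% names(summary)))
  sprintf("%-14s %-6s %-9s n=%-3d %8.*f ± %.*f",
          summary$parameter, summary$cohort, summary$timepoint, summary$n,
          digits, summary$mean, digits, summary$sem)
}
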