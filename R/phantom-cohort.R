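#' Built-in cohort simulation parameters
#'
#' Published summary statistics of the rodent cirrhosis study cohorts
#' (sham laparotomy vs bile duct ligation, BDL), used as generator
#' parameters: per-cohort baseline mean +/- SEM for each hepatic
#' haemodynamic parameter, and the within-subject mean change +/- SE after
#' the chosen intervention. `sem_n` / `effect_n` record the group sizes
#' the printed SEMs refer to, so the implied subject-level SD
#' (`SEM * sqrt(n)`) is faithful.
#'
#' @param intervention `"terlipressin"` (splanchnic vasoconstrictor;
#'   full-cohort baseline, n = 6 responders per group) or `"lps"`
#'   (lipopolysaccharide sepsis challenge modelling acute-on-chronic liver
#'   failure; n = 9 sham / 6 BDL completers).
#' @return Data frame with columns `parameter`, `cohort`, `baseline_mean`,
#'   `baseline_sem`, `sem_n`, `effect_mean`, `effect_se`, `effect_n`.
#'   Flows in ml/min/100 g liver, HA fraction in percent.
#' @export
default_cohort_parameters <- function(intervention = c("terlipressin", "lps")) {
  intervention <- match.arg(intervention)
  base <- data.frame(
    parameter = rep(c("pv_flow", "ha_flow", "ha_fraction", "tlbf"), each = 2),
    cohort = rep(c("sham", "BDL"), 4),
    baseline_mean = c(181.4, 68.5, 33.0, 83.8, 14.4, 51.5, 214.3, 152.3),
    baseline_sem = c(12.1, 10.1, 11.3, 19.1, 4.4, 6.8, 16.7, 18.7),
    sem_n = rep(c(16L, 18L), 4),
    stringsAsFactors = FALSE
  )
  if (intervention == "terlipressin") {
    eff <- data.frame(
      parameter = base$parameter, cohort = base$cohort,
      effect_mean = c(-90.3, -31.0, 92.8, -34.4, 38.8, -8.3, 2.5, -65.5),
      effect_se = c(11.1, 8.0, 21.3, 7.5, 6.5, 8.3, 14.0, 8.5),
      effect_n = rep(6L, 8), stringsAsFactors = FALSE
    )
  } else {
    eff <- data.frame(
      parameter = base$parameter, cohort = base$cohort,
      effect_mean = c(29.5, 6.44, 38.8, -64.99, 2.9, -20.9, 67.8, -58.6),
      effect_se = c(20.5, 25.1, 34.3, 42.05, 6.1, 7.5, 28.2, 34.6),
      effect_n = rep(c(9L, 6L), 4), stringsAsFactors = FALSE
    )
  }
  merge(base, eff, by = c("parameter", "cohort"), sort = FALSE)
}

#' Specify a two-cohort repeated-measures simulation
#'
#' @param parameters Data frame with one row per (parameter, cohort):
#'   columns `parameter`, `cohort`, `baseline_mean`, `baseline_sem`,
#'   `sem_n` (group size the SEM refers to; defaults to `n_per_group`),
#'   and optionally `effect_mean`, `effect_se`, `effect_n` for the
#'   within-subject change (omitted -> baseline only). See
#'   [default_cohort_parameters()].
#' @param n_per_group Simulated subjects per cohort (>= 2); scalar or
#'   named by cohort.
#' @param correlation Correlation in `[0, 1)` between a subject's baseline
#'   value and its within-subject change.
#' @return A `cohort_sim_spec` object.
#' @export
cohort_sim_spec <- function(parameters, n_per_group, correlation = 0.5) {
  req <- c("parameter", "cohort", "baseline_mean", "baseline_sem")
  if (!is.data.frame(parameters) || !all(req %in% names(parameters))) {
    stop("`parameters` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  parameters <- as.data.frame(parameters)
  if (any(parameters$baseline_sem < 0)) {
    stop("`baseline_sem` must be >= 0", call. = FALSE)
  }
  has_effect <- "effect_mean" %in% names(parameters)
  if (has_effect) {
    if (!"effect_se" %in% names(parameters)) {
      stop("`effect_mean` given without `effect_se`", call. = FALSE)
    }
    if (any(parameters$effect_se < 0)) stop("`effect_se` must be >= 0", call. = FALSE)
  }
  cohorts <- unique(parameters$cohort)
  if (is.null(names(n_per_group))) {
    n_per_group <- stats::setNames(rep_len(as.integer(n_per_group),
                                           length(cohorts)), cohorts)
  } else {
    n_per_group <- vapply(cohorts, function(g) as.integer(n_per_group[[g]]), 1L)
  }
  if (any(is.na(n_per_group)) || any(n_per_group < 2L)) {
    stop("`n_per_group` must be >= 2 for every cohort", call. = FALSE)
  }
  if (!"sem_n" %in% names(parameters)) {
    parameters$sem_n <- n_per_group[parameters$cohort]
  }
  if (has_effect && !"effect_n" %in% names(parameters)) {
    parameters$effect_n <- parameters$sem_n
  }
  if (!is.numeric(correlation) || length(correlation) != 1L ||
      correlation < 0 || correlation >= 1) {
    stop("`correlation` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(parameters = parameters, n_per_group = n_per_group,
         correlation = correlation, has_effect = has_effect),
    class = "cohort_sim_spec"
  )
}

#' Simulate a two-cohort repeated-measures table
#'
#' Per subject, the baseline value is drawn from
#' `Normal(baseline_mean, baseline_sem * sqrt(sem_n))` — the subject-level
#' SD implied by the printed SEM at its group size. The post value is
#' baseline plus a within-subject change with mean `effect_mean` and SD
#' `effect_se * sqrt(effect_n)`, correlated with the subject's baseline at
#' the specified correlation. Values for different parameters of the same
#' subject are drawn independently (documented limitation).
#'
#' @param spec A [cohort_sim_spec()].
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   tables.
#' @return Long-format `cohort_table` data frame with columns
#'   `subject_id`, `cohort`, `timepoint` (`baseline` / `post`),
#'   `parameter`, `value`.
#' @export
synthesize_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_optional_seed(seed, {
    rows <- vector("list", nrow(spec$parameters))
    for (i in seq_len(nrow(spec$parameters))) {
      p <- spec$parameters[i, ]
      n <- spec$n_per_group[[p$cohort]]
      ids <- sprintf("%s_%02d", p$cohort, seq_len(n))
      sd_b <- p$baseline_sem * sqrt(p$sem_n)
      b <- stats::rnorm(n, p$baseline_mean, sd_b)
      out <- data.frame(subject_id = ids, cohort = p$cohort,
                        timepoint = "baseline", parameter = p$parameter,
                        value = b, stringsAsFactors = FALSE)
      if (spec$has_effect && is.finite(p$effect_mean)) {
        sd_d <- p$effect_se * sqrt(p$effect_n)
        z_b <- if (sd_b > 0) (b - p$baseline_mean) / sd_b else rep(0, n)
        rho <- spec$correlation
        d <- p$effect_mean +
          sd_d * (rho * z_b + sqrt(1 - rho^2) * stats::rnorm(n))
        out <- rbind(out, data.frame(
          subject_id = ids, cohort = p$cohort, timepoint = "post",
          parameter = p$parameter, value = b + d, stringsAsFactors = FALSE))
      }
      rows[[i]] <- out
    }
    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
    class(tbl) <- c("cohort_table", "data.frame")
    tbl
  })
}
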