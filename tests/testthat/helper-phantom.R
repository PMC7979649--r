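# Shared fixtures, built in code at test time.

# Small hepatic phantom: coarse grid, few phases, fast to synthesize.
tiny_phantom <- function(seed = NULL, noise_sd = 0, background = NULL,
                         n_phases = 6L, pixel_spacing = 0.3,
                         matrix_size = 24L, ...) {
  specs <- hepatic_vessel_specs(n_phases = n_phases, ...)
  synthesize_pcmri(specs, pixel_spacing = pixel_spacing,
                   matrix_size = matrix_size, background = background,
                   noise_sd = noise_sd, seed = seed)
}

# Dataset with a spatially uniform through-plane velocity, for
# hand-calculable flow integrals.
uniform_dataset <- function(v_cm_s, venc = 33, nx = 8L, ny = 8L,
                            n_phases = 3L, pixel_spacing = 0.208) {
  enc <- array(pi * v_cm_s / venc, dim = c(nx, ny, n_phases))
  pcmri_dataset(magnitude = array(1, dim = c(nx, ny, n_phases)),
                phase_pos = wrap_phase(enc), phase_neg = wrap_phase(-enc),
                venc = venc, pixel_spacing = pixel_spacing)
}

# Random 2x2 mixed-design cohort table (two cohorts, two timepoints).
random_cohort_table <- function(n1 = 5L, n2 = 5L, effect_a = 0,
                                effect_b = 0, sd = 1) {
  ids <- c(sprintf("a_%02d", seq_len(n1)), sprintf("b_%02d", seq_len(n2)))
  cohort <- rep(c("a", "b"), c(n1, n2))
  base <- rnorm(n1 + n2, 10, sd)
  post <- base + rep(c(effect_a, effect_b), c(n1, n2)) + rnorm(n1 + n2, 0, sd)
  structure(
    data.frame(
      subject_id = rep(ids, 2), cohort = rep(cohort, 2),
      timepoint = rep(c("baseline", "post"), each = n1 + n2),
      parameter = "x", value = c(base, post), stringsAsFactors = FALSE),
    class = c("cohort_table", "data.frame"))
}

# Independent interaction-F oracle via stats::aov (balanced designs).
aov_interaction_F <- function(table, parameter = "x") {
  tab <- table[table$parameter == parameter, ]
  tab$cohort <- factor(tab$cohort)
  tab$timepoint <- factor(tab$timepoint)
  tab$subject_id <- factor(tab$subject_id)
  fit <- stats::aov(value ~ cohort * timepoint + Error(subject_id / timepoint),
                    data = tab)
  s <- summary(fit)[["Error: subject_id:timepoint"]][[1]]
  unname(s["cohort:timepoint", "F value"])
}

# Brute-force sums-of-squares interaction F for a balanced 2x2 mixed
# design, computed from cell/subject means with no shortcuts.
ss_interaction_F <- function(table, parameter = "x") {
  tab <- table[table$parameter == parameter, ]
  g <- sort(unique(tab$cohort)); tp <- c("baseline", "post")
  cell <- function(gg, tt) tab$value[tab$cohort == gg & tab$timepoint == tt]
  n_g <- vapply(g, function(gg) length(cell(gg, "baseline")), 0L)
  stopifnot(length(unique(n_g)) == 1L)  # balanced only
  n <- n_g[1]
  m <- outer(g, tp, Vectorize(function(gg, tt) mean(cell(gg, tt))))
  m_g <- rowMeans(m); m_t <- colMeans(m); m_all <- mean(m)
  ss_int <- n * sum((m - outer(m_g, rep(1, 2)) -
                       outer(rep(1, 2), m_t) + m_all)^2)
  # residual: subject x timepoint within groups
  ss_err <- 0
  for (gi in seq_along(g)) {
    y <- cbind(cell(g[gi], "baseline"), cell(g[gi], "post"))
    subj_mean <- rowMeans(y)
    for (ti in 1:2) {
      ss_err <- ss_err + sum((y[, ti] - subj_mean - m[gi, ti] + m_g[gi])^2)
    }
  }
  df_err <- (2 - 1) * (2 * n - 2)
  unname((ss_int / 1) / (ss_err / df_err))
}

# Hand-written Welch statistic (the formula, not t.test).
welch_by_hand <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p.value = p)
}
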