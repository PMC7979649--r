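test_that("waveform is constant at zero pulsatility and refuses velocity wrap", {
  sp <- vessel_spec("pv", mean_flow = 30, radius = 1.5, pulsatility = 0)
  expect_equal(make_waveform(sp), rep(30, 12))

  # mean flow 30 ml/min through a 0.5 mm radius vessel peaks far above 33 cm/s
  expect_error(vessel_spec("pv", mean_flow = 30, radius = 0.5),
               "reaches Venc")
  expect_error(vessel_spec("pv", mean_flow = 30, radius = 1.5,
                           pulsatility = 1.2), "pulsatility")
  expect_error(vessel_spec("pv", mean_flow = 30, radius = 1.5, n_phases = 1),
               "n_phases")
})

test_that("waveform mean equals the prescribed mean flow to machine precision", {
  set.seed(42)
  for (i in 1:25) {
    sp <- vessel_spec("pv", mean_flow = runif(1, 5, 40),
                      radius = runif(1, 1.2, 2),
                      pulsatility = runif(1, 0, 0.9),
                      n_phases = sample(2:24, 1))
    wf <- make_waveform(sp)
    expect_length(wf, sp$n_phases)
    expect_lt(abs(mean(wf) - sp$mean_flow) / abs(sp$mean_flow), 1e-12)
  }
})

test_that("zero-flow noiseless phantom decodes to zero velocity throughout", {
  specs <- list(vessel_spec("pv", mean_flow = 0, radius = 1.5, n_phases = 4))
  ph <- synthesize_pcmri(specs, pixel_spacing = 0.3, matrix_size = 16)
  for (k in 1:4) {
    expect_equal(decode_velocity(ph$datasets$pv, k), matrix(0, 16, 16))
  }
  expect_equal(as.numeric(flow_curve(ph$datasets$pv, ph$rois$pv)), rep(0, 4))
})

test_that("ground-truth conservation holds exactly by construction", {
  ph <- tiny_phantom(seed = 11, noise_sd = 0.05)
  tr <- ph$truth
  expect_equal(tr$waveforms$supra_ivc,
               tr$waveforms$infra_ivc + tr$waveforms$pv + tr$ha_curve,
               tolerance = 1e-14)
  expect_equal(tr$tlbf, tr$mean_flows[["pv"]] + tr$ha_flow, tolerance = 1e-14)
})

test_that("a fixed seed reproduces the phantom bit-identically", {
  a <- tiny_phantom(seed = 99, noise_sd = 0.08, background = c(0.1, 0.05))
  b <- tiny_phantom(seed = 99, noise_sd = 0.08, background = c(0.1, 0.05))
  expect_identical(a$datasets$pv$phase_pos, b$datasets$pv$phase_pos)
  expect_identical(a$datasets$supra_ivc$phase_neg, b$datasets$supra_ivc$phase_neg)
  c <- tiny_phantom(seed = 100, noise_sd = 0.08)
  expect_false(identical(a$datasets$pv$phase_pos, c$datasets$pv$phase_pos))
})

test_that("vessels that do not fit in the field of view are refused", {
  specs <- list(vessel_spec("pv", mean_flow = 20, radius = 1.5))
  expect_error(synthesize_pcmri(specs, pixel_spacing = 0.2, matrix_size = 8),
               "field of view")
})

test_that("stored phase maps stay in the principal interval", {
  ph <- tiny_phantom(seed = 3, noise_sd = 0.3, background = c(0.5, 0.3, -0.3))
  for (ds in ph$datasets) {
    expect_true(all(ds$phase_pos > -pi & ds$phase_pos <= pi))
    expect_true(all(ds$phase_neg > -pi & ds$phase_neg <= pi))
  }
})

test_that("cine phantom recovers prescribed volumes and degenerates cleanly", {
  spec <- lv_phantom_spec(edv = 0.66, esv = 0.25, n_phases = 8)
  sim <- synthesize_cine(spec)
  endo <- volume_curve(sim$study, "endocardial")
  expect_equal(max(endo), sim$truth$edv, tolerance = 0.05)
  expect_equal(min(endo), sim$truth$esv, tolerance = 0.05)

  # static heart: EDV = ESV gives SV = 0, EF = 0
  static <- synthesize_cine(lv_phantom_spec(edv = 0.4, esv = 0.4, n_phases = 4))
  cf <- systolic_parameters(volume_curve(static$study, "endocardial"),
                            volume_curve(static$study, "epicardial"),
                            heart_rate = 300, body_weight = 400)
  expect_equal(cf$sv, 0)
  expect_equal(cf$ef, 0)

  # myocardial shell volume is constant across the cycle
  epi <- volume_curve(sim$study, "epicardial")
  wall <- epi - endo
  expect_lt(diff(range(wall)) / mean(wall), 0.05)

  expect_error(synthesize_cine(lv_phantom_spec(edv = 0.02, esv = 0.001)),
               "infeasible")
  expect_error(lv_phantom_spec(edv = 0.4, esv = 0.5), "esv")
})

test_that("doubling in-plane resolution shrinks the pixelation error", {
  spec <- lv_phantom_spec(n_phases = 2)
  err <- vapply(c(1, 2), function(f) {
    sim <- synthesize_cine(spec, pixel_spacing = c(0.313, 0.625) / f,
                           matrix_size = c(128, 64) * f)
    endo <- volume_curve(sim$study, "endocardial")
    abs(max(endo) - sim$truth$endo_disc_ml[1])
  }, 0)
  expect_lte(err[2], err[1] / 2)
})

test_that("cohort generator matches its specification moments", {
  pars <- data.frame(parameter = "x", cohort = c("sham", "BDL"),
                     baseline_mean = c(100, 60), baseline_sem = c(3, 2),
                     sem_n = c(16L, 18L), effect_mean = c(-10, 5),
                     effect_se = c(2, 2), effect_n = c(6L, 6L))
  # degenerate: zero variances give exactly the specified means
  pars0 <- transform(pars, baseline_sem = 0, effect_se = 0)
  tbl0 <- synthesize_cohort(cohort_sim_spec(pars0, n_per_group = 4), seed = 1)
  expect_equal(tbl0$value[tbl0$cohort == "sham" & tbl0$timepoint == "baseline"],
               rep(100, 4))
  expect_equal(tbl0$value[tbl0$cohort == "BDL" & tbl0$timepoint == "post"],
               rep(65, 4))

  # law of large numbers: sample means within 3 standard errors at n = 1e4
  n <- 10000L
  tbl <- synthesize_cohort(cohort_sim_spec(pars, n_per_group = n), seed = 2)
  for (g in c("sham", "BDL")) {
    p <- pars[pars$cohort == g, ]
    b <- tbl$value[tbl$cohort == g & tbl$timepoint == "baseline"]
    se <- p$baseline_sem * sqrt(p$sem_n) / sqrt(n)
    expect_lt(abs(mean(b) - p$baseline_mean), 3 * se)
    d <- tbl$value[tbl$cohort == g & tbl$timepoint == "post"] - b
    se_d <- p$effect_se * sqrt(p$effect_n) / sqrt(n)
    expect_lt(abs(mean(d) - p$effect_mean), 3 * se_d)
  }
  # fixed seed is bit-identical
  expect_identical(tbl0, synthesize_cohort(cohort_sim_spec(pars0, 4), seed = 1))
})
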