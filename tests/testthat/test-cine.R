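test_that("disc summation reproduces the cylinder hand calculation", {
  # 3 slices, each a 10 x 4 pixel rectangle of 0.5 x 0.5 mm pixels, 2 mm thick:
  # area = 10 mm^2 = 0.1 cm^2 per slice, V = 3 * 0.1 * 0.2 = 0.06 ml per phase
  nx <- 16L; ny <- 8L
  endo <- array(FALSE, c(nx, ny, 3, 2))
  endo[4:13, 3:6, , ] <- TRUE
  study <- cine_study(endo = endo, epi = endo, pixel_spacing = 0.5,
                      slice_thickness = 2, heart_rate = 300, body_weight = 400)
  expect_equal(volume_curve(study, "endocardial"), rep(0.06, 2))

  # empty masks give zero volume
  study0 <- cine_study(array(FALSE, c(4, 4, 2, 2)), array(FALSE, c(4, 4, 2, 2)),
                       pixel_spacing = 0.5, slice_thickness = 2,
                       heart_rate = 300, body_weight = 400)
  expect_equal(volume_curve(study0, "endocardial"), c(0, 0))
})

test_that("cine study validates mask containment and completeness", {
  endo <- array(TRUE, c(4, 4, 2, 2))
  epi <- array(FALSE, c(4, 4, 2, 2))
  expect_error(cine_study(endo, epi, 0.5, 2, 300, 400), "outside")
  bad <- array(TRUE, c(4, 4, 2, 2)); bad[1, 1, 1, 1] <- NA
  expect_error(cine_study(bad, array(TRUE, c(4, 4, 2, 2)), 0.5, 2, 300, 400),
               "missing")
  expect_error(cine_study(endo, array(TRUE, c(4, 4, 2, 3)), 0.5, 2, 300, 400),
               "identical")
})

test_that("ellipsoid phantom volume converges to the analytic value", {
  spec <- lv_phantom_spec(edv = 0.66, esv = 0.25, n_phases = 2, n_slices = 6)
  sim <- synthesize_cine(spec)
  edv_hat <- max(volume_curve(sim$study, "endocardial"))
  expect_equal(edv_hat, 0.66, tolerance = 0.05)
  # thinner slices reduce the through-plane bias of the disc reference
  coarse <- abs(disc_reference_volume(0.66, 6, 2) - 0.66)
  fine <- abs(disc_reference_volume(0.66, 24, 0.5) - 0.66)
  expect_lt(fine, coarse)
})

test_that("systolic parameters follow their defining arithmetic", {
  cf <- systolic_parameters(endo_curve = c(0.8, 0.6, 0.4, 0.6),
                            epi_curve = c(1.8, 1.6, 1.4, 1.6),
                            heart_rate = 300, body_weight = 500)
  expect_equal(cf$edv, 0.8)
  expect_equal(cf$esv, 0.4)
  expect_equal(cf$sv, 0.4)
  expect_equal(cf$ef, 50)
  expect_equal(cf$co, 120)
  # myocardial volume 1.0 cm^3 at end diastole weighs 1.05 g
  expect_equal(cf$lv_mass, 1.05)
  expect_equal(cf$cardiac_index, 120 / 0.5)
  expect_equal(cf$lv_mass_index, 1.05 / 0.5)

  cf2 <- systolic_parameters(c(1.0, 0.5), c(2.0, 1.5), heart_rate = 300,
                             body_weight = 500)
  expect_equal(cf2$sv, 0.5)
  expect_equal(cf2$co, 150)
  expect_equal(cf2$cardiac_index, 300)

  expect_error(systolic_parameters(c(0, 0), c(1, 1), 300, 500), "EDV")
  expect_error(systolic_parameters(c(1, 0.5), c(2, 1.5), 300, 0), "body_weight")
  expect_error(systolic_parameters(1, 2, 300, 500), "length")
})

test_that("ejection fraction stays in (0, 100] and SV is non-negative", {
  set.seed(5)
  for (i in 1:20) {
    endo <- runif(8, 0.2, 1)
    epi <- endo + runif(8, 0.3, 0.8)
    cf <- systolic_parameters(endo, epi, 300, 450)
    expect_gte(cf$sv, 0)
    expect_gt(cf$ef, 0)
    expect_lte(cf$ef, 100)
    expect_gte(cf$lv_mass, 0)
  }
})
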