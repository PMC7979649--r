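test_that("velocity decoding follows the opposite-encoding convention", {
  # equal encodings decode to zero
  ds0 <- uniform_dataset(0)
  expect_equal(decode_velocity(ds0, 1), matrix(0, 8, 8))

  # +pi/2 / -pi/2 at Venc 33 is 16.5 cm/s
  ds <- uniform_dataset(16.5, venc = 33)
  expect_equal(decode_velocity(ds, 1), matrix(16.5, 8, 8), tolerance = 1e-12)

  # adding the same background field to both encodings cancels exactly
  nx <- 8L; ny <- 8L
  bg <- outer(seq(-0.4, 0.4, length.out = nx),
              seq(-0.3, 0.3, length.out = ny), `+`)
  enc <- pi * 12 / 33
  with_bg <- pcmri_dataset(
    magnitude = array(1, c(nx, ny, 1)),
    phase_pos = array(wrap_phase(enc + bg), c(nx, ny, 1)),
    phase_neg = array(wrap_phase(-enc + bg), c(nx, ny, 1)),
    venc = 33, pixel_spacing = 0.208)
  expect_equal(decode_velocity(with_bg, 1), matrix(12, nx, ny),
               tolerance = 1e-12)
})

test_that("decoding is linear in the encoded phase difference", {
  for (alpha in c(0.25, 0.5, 2)) {
    v <- 6
    d1 <- uniform_dataset(v); d2 <- uniform_dataset(alpha * v)
    expect_equal(decode_velocity(d2, 1), alpha * decode_velocity(d1, 1),
                 tolerance = 1e-12)
  }
})

test_that("decode validates its inputs", {
  ds <- uniform_dataset(5)
  expect_error(decode_velocity(ds, 0), "phase_index")
  expect_error(decode_velocity(ds, 4), "phase_index")
  expect_error(pcmri_dataset(array(1, c(4, 4, 2)), array(0, c(4, 4, 2)),
                             array(0, c(4, 5, 2)), venc = 33,
                             pixel_spacing = 0.2), "identical dimensions")
  expect_error(pcmri_dataset(array(1, c(4, 4, 2)), array(4, c(4, 4, 2)),
                             array(0, c(4, 4, 2)), venc = 33,
                             pixel_spacing = 0.2), "wrap_phase")
})

test_that("ROI flow integration reproduces the hand unit conversion", {
  # uniform 10 cm/s over 20 pixels of 0.208 mm: 10 * 20 * 0.0208^2 * 60
  ds <- uniform_dataset(10, venc = 33, nx = 10L, ny = 10L, n_phases = 2L)
  roi <- matrix(FALSE, 10, 10); roi[3:7, 4:7] <- TRUE  # 20 pixels, off-border
  q <- flow_curve(ds, roi)
  expect_equal(as.numeric(q), rep(10 * 20 * 0.0208^2 * 60, 2),
               tolerance = 1e-10)
  expect_equal(as.numeric(q), rep(5.19168, 2), tolerance = 1e-6)

  expect_error(flow_curve(ds, matrix(FALSE, 10, 10)), "empty ROI")
  border <- matrix(FALSE, 10, 10); border[1, 1] <- TRUE
  expect_warning(flow_curve(ds, border), "border")
})

test_that("Poiseuille flow integration converges to the analytic flux", {
  spec <- vessel_spec("pv", mean_flow = 29.9, radius = 1.4, pulsatility = 0,
                      n_phases = 2)
  err <- vapply(c(0.28, 0.14, 0.07), function(px) {
    ph <- synthesize_pcmri(list(spec), pixel_spacing = px,
                           matrix_size = 2L * ceiling(1.9 / px))
    abs(mean_flow(flow_curve(ph$datasets$pv, ph$rois$pv)) - 29.9) / 29.9
  }, 0)
  expect_lt(err[2], 0.02)   # pixel = r/10
  expect_lt(err[3], err[1]) # finer grids do better
})

test_that("cycle-mean flow is the arithmetic mean of the samples", {
  expect_equal(mean_flow(rep(7.5, 10)), 7.5)
  # zero-mean sinusoid sampled over a full cycle leaves the mean unchanged
  m <- 12; s <- m + 3 * sin(2 * pi * (0:11) / 12)
  expect_equal(mean_flow(s), m, tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(17)
  expect_equal(mean_flow(x), sum(x) / 17)
  expect_error(mean_flow(numeric(0)), "empty")
  expect_error(mean_flow(c(1, NA)), "finite")
})
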