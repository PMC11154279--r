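# divergent-source ray model: focal spot, magnification, transmittance,
# fluence patterns, penumbra overlap

test_that("FWTM conversion matches the Gaussian tenth-maximum width", {
  expect_equal(fwtm_from_sigma(0.58), 0.58 * sqrt(8 * log(10)),
               tolerance = 1e-12)
  expect_equal(signif(fwtm_from_sigma(0.58), 2), 2.5)
  expect_identical(fwtm_from_sigma(0), 0)
  expect_equal(fwtm_from_sigma(1), 4.291932, tolerance = 1e-6)
  expect_error(fwtm_from_sigma(-0.1), "non-negative")
})

test_that("magnification follows the intersecting-lines theorem", {
  expect_equal(magnification(212, 6), 218 / 212, tolerance = 1e-12)
  expect_equal(round(magnification(212, 6), 2), 1.03)
  expect_identical(magnification(212, 0), 1)
  # a 400 um period projects to 430 um a distance 15.9 mm downstream
  expect_equal(400 * magnification(212, 15.9), 430, tolerance = 1e-3)
  expect_error(magnification(0, 5), "positive")
})

test_that("source profile is a normalised Gaussian density", {
  fs <- focal_spot(0.58)
  expect_equal(source_profile(0, fs), 1 / (0.58 * sqrt(2 * pi)))
  x <- seq(-6 * 0.58, 6 * 0.58, by = 1e-3)
  expect_equal(sum(source_profile(x, fs)) * 1e-3, 1, tolerance = 1e-6)
  expect_equal(source_profile(0.58, fs) / source_profile(0, fs),
               exp(-0.5), tolerance = 1e-12)
  expect_error(source_profile(0, focal_spot(0)), "point source")
})

test_that("collimator transmittance is periodic, leaky, and apertured", {
  col <- collimator()
  expect_identical(collimator_transmittance(0, col), 1)
  x <- seq(-2, 2, by = 0.013)
  expect_equal(collimator_transmittance(x, col, field_mm = 20),
               collimator_transmittance(x + 0.4, col, field_mm = 20))
  septum <- collimator_transmittance(0.2, col, energy_kev = 100)
  expect_lt(septum, 1e-3)
  # leakage equals Beer-Lambert through the 7 mm septum
  mu_w <- mass_attenuation("tungsten", 100) * 19.30 / 10
  expect_equal(septum, exp(-mu_w * 7), tolerance = 1e-10)
  expect_identical(collimator_transmittance(11, col, field_mm = 20), 0)
  expect_error(collimator_transmittance(0.2, col, energy_kev = 5),
               "outside the tabulated range")
})

test_that("fluence pattern: fast path agrees with the direct integral", {
  g <- toy_geometry(sigma_mm = 0.3)
  for (y in c(225, 240, 260)) {
    pq <- fluence_pattern(g, y, x_range_mm = 1.4, method = "quadrature")
    pc <- fluence_pattern(g, y, x_range_mm = 1.4, method = "convolution")
    expect_lt(max(abs(pq$relative_fluence - pc$relative_fluence)) /
                max(pq$relative_fluence), 1e-3)
  }
})

test_that("fluence pattern: normalisation, symmetry, pinhole limit", {
  g <- beam_geometry()
  pat <- fluence_pattern(g, 250, x_range_mm = 3)
  expect_equal(own_period_mean(pat$position_um, pat$relative_fluence,
                               attr(pat, "period_um")), 1, tolerance = 1e-6)
  # symmetric about the central slit projection
  expect_lt(max(abs(pat$relative_fluence - rev(pat$relative_fluence))) /
              max(pat$relative_fluence), 5e-3)
  # point source: the pattern is the magnified transmittance
  g0 <- beam_geometry(focal_spot = focal_spot(0),
                      collimator = collimator(leakage = 0))
  p0 <- fluence_pattern(g0, 250, x_range_mm = 2)
  on_duty <- p0$relative_fluence > 0.5 * max(p0$relative_fluence)
  duty <- mean(on_duty[abs(p0$position_um) < attr(p0, "period_um") / 2])
  expect_equal(duty, 30 / 400, tolerance = 0.05)
})

test_that("projected period equals collimator ctc times magnification", {
  g <- beam_geometry(focal_spot = focal_spot(0.2))
  for (y in c(230, 260)) {
    pat <- fluence_pattern(g, y, x_range_mm = 2.2)
    m <- profile_metrics(tibble::tibble(position_um = pat$position_um,
                                        dose = pat$relative_fluence))
    expect_equal(m$ctc_um, 400 * y / 212, tolerance = 1e-3)
  }
})

test_that("duty cycle of the pinhole pattern is depth independent", {
  g0 <- beam_geometry(focal_spot = focal_spot(0),
                      collimator = collimator(leakage = 0))
  duty <- vapply(c(220, 250, 290), function(y) {
    p <- fluence_pattern(g0, y, x_range_mm = 2)
    sel <- abs(p$position_um) < attr(p, "period_um") / 2
    mean(p$relative_fluence[sel] > 0.5 * max(p$relative_fluence))
  }, numeric(1))
  expect_equal(duty, rep(duty[1], 3), tolerance = 0.05)
})

test_that("penumbra overlap depth matches the closed-form solution", {
  d <- 2.5
  g <- beam_geometry(focal_spot = focal_spot(d / sqrt(8 * log(10))))
  # oracle: slit*(y/sd) + d*(y-sd)/sd = ctc*(y/sd) solved for y - sd
  oracle <- d * 212 / (d - 0.4 + 0.03) - 212
  expect_equal(penumbra_overlap_depth(g), oracle, tolerance = 1e-9)
  expect_equal(oracle, 36.8, tolerance = 1e-2)
  # parallel-edge limit: no overlap
  expect_identical(penumbra_overlap_depth(
    beam_geometry(focal_spot = focal_spot(0))), Inf)
  # deeper sources overlap sooner
  depths <- vapply(c(2, 2.5, 3) / sqrt(8 * log(10)), function(s) {
    penumbra_overlap_depth(beam_geometry(focal_spot = focal_spot(s)))
  }, numeric(1))
  expect_true(all(diff(depths) < 0))
})
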