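# electron kernel, profile reconstruction, and metric extraction

test_that("electron kernel is a unit-integral symmetric density", {
  k <- electron_kernel(std_spectrum(), density = 1.19)
  pitch <- attr(k, "pitch_um")
  expect_equal(sum(k$weight) * pitch, 1, tolerance = 1e-9)
  expect_equal(k$weight, rev(k$weight))
  expect_true(all(k$weight >= 0))
})

test_that("kernel width scales inversely with density", {
  sp <- std_spectrum()
  w1 <- kernel_fwhm_um(electron_kernel(sp, density = 1))
  w2 <- kernel_fwhm_um(electron_kernel(sp, density = 2))
  expect_equal(w1 / w2, 2, tolerance = 0.01)
})

test_that("convolving a constant with the kernel leaves it unchanged", {
  k <- electron_kernel(std_spectrum(), density = 1.19)
  kw <- k$weight / sum(k$weight)
  out <- mrtplan:::conv_same(rep(3.5, 2000), kw)
  mid <- out[500:1500]
  expect_equal(mid, rep(3.5, length(mid)), tolerance = 1e-9)
})

test_that("degenerate reconstruction: delta kernel and point source", {
  g0 <- beam_geometry(focal_spot = focal_spot(0),
                      collimator = collimator(leakage = 0))
  pr <- reconstruct_profile(2, 0.5, g0, kernel = NULL, y_mm = 250)
  mag <- 250 / 212
  # peak = d_primary / duty cycle + pedestal, valley = pedestal
  expect_equal(max(pr$dose), 2 * 400 / 30 + 0.5, tolerance = 0.02)
  expect_equal(min(pr$dose), 0.5, tolerance = 1e-9)
  m <- profile_metrics(pr)
  expect_equal(m$ctc_um, 400 * mag, tolerance = 1e-3)
})

test_that("a kernel much wider than the period flattens the profile", {
  g <- beam_geometry()
  wide <- tibble::tibble(offset_um = seq(-2000, 2000, by = 4),
                         weight = rep(1, 1001))
  k <- electron_kernel(std_spectrum(), 1.19, pitch_um = 4, table = wide)
  pr <- reconstruct_profile(1, 0.2, g, k, y_mm = 230)
  m <- profile_metrics(pr)
  expect_lt(m$pvdr, 1.1)
  expect_equal(own_period_mean(pr$position_um, pr$dose,
                               attr(pr, "period_um")), 1.2, tolerance = 0.02)
})

test_that("reconstruction agrees with the direct-integral oracle", {
  g <- toy_geometry(sigma_mm = 0.3)
  k <- electron_kernel(std_spectrum(), 1.19)
  a <- reconstruct_profile(1, 0.1, g, k, y_mm = 240, span_periods = 5,
                           method = "convolution")
  b <- reconstruct_profile(1, 0.1, g, k, y_mm = 240, span_periods = 5,
                           method = "quadrature")
  expect_lt(max(abs(a$dose - b$dose)) / max(a$dose), 5e-3)
})

test_that("period mean of the reconstructed profile conserves the voxel dose", {
  g <- beam_geometry()
  k <- electron_kernel(std_spectrum(), 1.19)
  for (y in c(225, 250, 275)) {
    pr <- reconstruct_profile(0.8, 0.3, g, k, y_mm = y)
    expect_equal(own_period_mean(pr$position_um, pr$dose,
                                 attr(pr, "period_um")),
                 0.8 + 0.3, tolerance = 1e-3)
  }
})

test_that("the three convolution factors commute", {
  g <- beam_geometry()
  pitch <- 0.001
  x <- seq(-3, 3, by = pitch)
  trans <- mrtplan:::collimator_transmittance_aa(
    x / (250 / 212), g$collimator, 20, pitch_mm = pitch / (250 / 212))
  sig <- 0.58 * 38 / 212
  half_k <- ceiling(5 * sig / pitch)
  xg <- (-half_k:half_k) * pitch
  gk <- stats::dnorm(xg, sd = sig); gk <- gk / sum(gk)
  ek <- electron_kernel(std_spectrum(), 1.19)
  ew <- ek$weight / sum(ek$weight)
  ab <- mrtplan:::conv_same(mrtplan:::conv_same(trans, gk), ew)
  ba <- mrtplan:::conv_same(mrtplan:::conv_same(trans, ew), gk)
  # compare away from the boundary (finite-domain edge effects differ)
  trim <- (length(gk) + length(ew)) %/% 2 + 1
  sel <- trim:(length(ab) - trim)
  expect_equal(ab[sel], ba[sel], tolerance = 1e-9)
})

test_that("metrics recover an ideal rectangular array exactly", {
  prof <- rect_array_profile(width_um = 100, period_um = 400,
                             high = 10, low = 2)
  m <- profile_metrics(prof)
  expect_equal(m$peak_dose, 10, tolerance = 1e-6)
  expect_equal(m$valley_dose, 2, tolerance = 1e-6)
  expect_equal(m$pvdr, 5, tolerance = 1e-6)
  expect_equal(m$fwhm_um, 100, tolerance = 0.03)
  expect_equal(m$ctc_um, 400, tolerance = 1e-6)
  expect_equal(m$pvdr, m$peak_dose / m$valley_dose)
  m2 <- profile_metrics(prof, valley_mode = "central50")
  expect_equal(m2$valley_dose, 2, tolerance = 1e-6)
})

test_that("measured period 6 mm past the collimator shows the 3% magnification", {
  g <- beam_geometry()
  pr <- reconstruct_profile(1, 0.05, g, NULL, y_mm = 218)
  m <- profile_metrics(pr)
  expect_equal(m$ctc_um / 400, magnification(212, 6), tolerance = 3e-3)
})

test_that("FWHM and period grow with depth; scatter lowers PVDR", {
  g <- beam_geometry()
  k <- electron_kernel(std_spectrum(), 1.19)
  ms <- purrr::map_dfr(c(220, 235, 250, 265), function(y) {
    profile_metrics(reconstruct_profile(1, 0.1, g, k, y_mm = y))
  })
  expect_true(all(diff(ms$fwhm_um) > 0))
  expect_true(all(diff(ms$ctc_um) > 0))
  lo <- profile_metrics(reconstruct_profile(1, 0.05, g, k, y_mm = 240))
  hi <- profile_metrics(reconstruct_profile(1, 0.30, g, k, y_mm = 240))
  expect_gt(lo$pvdr, hi$pvdr)
})

test_that("coarse grids and degenerate profiles are rejected", {
  g <- beam_geometry()
  expect_error(reconstruct_profile(1, 0, g, NULL, 230, pitch_um = 10),
               "too coarse")
  flat <- tibble::tibble(position_um = 1:100, dose = rep(1, 100))
  expect_error(profile_metrics(flat), "peaks")
})
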