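# Monte Carlo photon transport and its deterministic companions

test_that("identical seeds give bit-identical dose grids", {
  ph <- small_pmma(c(20, 20, 10), vox = 2)
  sp <- std_spectrum()
  a <- simulate_photon_dose(ph, beam_geometry(), sp, 2e4, seed = 99)
  b <- simulate_photon_dose(ph, beam_geometry(), sp, 2e4, seed = 99)
  expect_identical(a$d_primary, b$d_primary)
  expect_identical(a$d_scatter, b$d_scatter)
  c <- simulate_photon_dose(ph, beam_geometry(), sp, 2e4, seed = 100)
  expect_false(identical(a$d_primary, c$d_primary))
})

test_that("input contracts are enforced", {
  ph <- small_pmma(c(10, 10, 10), vox = 2)
  sp <- std_spectrum()
  expect_error(simulate_photon_dose(ph, beam_geometry(), sp, 0, seed = 1),
               ">= 1")
  expect_error(simulate_photon_dose(ph, beam_geometry(), sp, 10), "seed")
})

test_that("slab-summed MC primary energy matches the analytic ray trace", {
  # near-parallel pencil beam: per-depth-slab primary energy deposition has
  # the closed form sum_E p(E) w(E) exp(-tau) (1 - exp(-mu dz)) f_tr(E) E
  sp <- std_spectrum()
  geom <- beam_geometry(field_mm = c(1, 1), focal_spot = focal_spot(0.01))
  ph <- small_pmma(c(10, 10, 20), vox = 2)
  dg <- simulate_photon_dose(ph, geom, sp, 2e5, seed = 3)
  mass_g <- 1.19 * (2 / 10)^3
  mc_slab <- apply(dg$d_primary, 3, sum) * mass_g * 1e-3 / mrtplan:::KEV_TO_J

  # independent oracle built from the cross-section tables
  e <- sp$energy_kev
  mu <- vapply(e, function(E) {
    max(mass_attenuation("pmma", E), mrtplan:::kn_mu_over_rho("pmma", E)) *
      1.19 / 10
  }, numeric(1))
  kn <- mrtplan:::kn_mu_over_rho("pmma", e) * 1.19 / 10
  pe <- pmax(mu - kn, 0)
  ftr <- (pe + kn * mrtplan:::kn_mean_transfer_fraction(e)) / mu
  duty <- 51 * 0.03 / 20
  leak <- vapply(e, function(E) exp(-mass_attenuation("tungsten", E) *
                                      19.3 / 10 * 7), numeric(1))
  wbar <- duty + (1 - duty) * leak
  z_front <- (0:9) * 2
  oracle <- vapply(seq_along(z_front), function(i) {
    tau <- mu * z_front[i]
    sum(sp$fluence * wbar * exp(-tau) * (1 - exp(-mu * 2)) * ftr * e)
  }, numeric(1))
  expect_equal(mc_slab / 2e5, oracle, tolerance = 0.05)
})

test_that("deterministic primary: inverse square in near-vacuum, monotone in PMMA", {
  sp <- std_spectrum()
  geom <- beam_geometry(field_mm = c(10, 10))
  air <- make_slab_phantom(c(20, 20, 40), "air", voxel_mm = 2)
  d <- primary_dose_deterministic(air, geom, sp)
  prof <- d[5, 5, ]
  y <- 212 + 4 + (seq_len(20) - 0.5) * 2
  expect_equal(prof / prof[1], (y[1] / y)^2, tolerance = 5e-3)
  pm <- primary_dose_deterministic(small_pmma(), beam_geometry(), sp)
  expect_true(all(diff(pm[8, 8, ]) < 0))
})

test_that("MC primary converges to the deterministic ray trace", {
  sp <- std_spectrum()
  geom <- beam_geometry()
  ph <- small_pmma(c(30, 30, 20), vox = 2)
  dg <- simulate_photon_dose(ph, geom, sp, 4e5, seed = 8)
  det <- primary_dose_deterministic(ph, geom, sp)
  sel_x <- 6:10
  mc <- apply(dg$d_primary[sel_x, sel_x, ], 3, mean)
  dt <- apply(det[sel_x, sel_x, ], 3, mean)
  expect_equal(mc / dt, rep(1, 10), tolerance = 0.04)
})

test_that("scatter grows with field size at matched depth", {
  sp <- std_spectrum()
  ph <- small_pmma(c(30, 30, 16), vox = 2)
  spr <- vapply(c(5, 10), function(f) {
    g <- beam_geometry(field_mm = c(f, f))
    dg <- simulate_photon_dose(ph, g, sp, 2e5, seed = 21)
    iz <- 5   # ~10 mm depth
    mean(dg$d_scatter[7:9, 7:9, iz]) / mean(dg$d_primary[7:9, 7:9, iz])
  }, numeric(1))
  expect_gt(spr[2], spr[1])
})

test_that("statistical uncertainty scales as one over root histories", {
  sp <- std_spectrum()
  ph <- small_pmma(c(20, 20, 10), vox = 2)
  g <- beam_geometry()
  u1 <- simulate_photon_dose(ph, g, sp, 1e5, seed = 4)$rel_uncertainty
  u2 <- simulate_photon_dose(ph, g, sp, 2e5, seed = 5)$rel_uncertainty
  sel <- !is.na(u1) & !is.na(u2) & u1 > 0 & u2 > 0
  ratio <- mean(u1[sel]^2) / mean(u2[sel]^2)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("kerma depth curve is log-linear after inverse-square correction", {
  sp <- std_spectrum()
  ph <- make_slab_phantom(c(30, 30, 60), "pmma", voxel_mm = 2)
  det <- primary_dose_deterministic(ph, beam_geometry(), sp)
  z <- (seq_len(30) - 0.5) * 2
  y <- 212 + 4 + z
  corrected <- log(det[8, 8, ] * (y / 212)^2)
  fit <- stats::lm(corrected ~ z)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("single-scatter estimate: zero without matter, builds up, bounded", {
  sp <- std_spectrum()
  geom <- beam_geometry(field_mm = c(10, 10))
  air <- make_slab_phantom(c(20, 20, 20), "air", voxel_mm = 2,
                           density = 1e-7)
  s0 <- scatter_kernel_estimate(air, geom, sp)
  expect_true(all(s0 == 0))
  expect_true(attr(s0, "approximate"))
  ph <- make_slab_phantom(c(40, 40, 60), "pmma", voxel_mm = 2)
  s <- scatter_kernel_estimate(ph, geom, sp)
  centre <- s[10, 10, ]
  expect_gt(which.max(centre), 2)             # interior build-up maximum
  expect_lt(which.max(centre), 25)
  # conservation: absorbed scatter energy cannot exceed the energy emitted
  # into scattered photons (itself bounded by one unit-fluence history)
  mass_kg <- ph$density * (2 / 10)^3 * 1e-3
  tot_kev <- sum(s * mass_kg) / mrtplan:::KEV_TO_J
  expect_lt(tot_kev, spectrum_mean_energy(sp))
})
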