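# plan aggregation, depth reports, positioning

test_that("plan report identities hold to machine precision", {
  ph <- make_mouse_head_phantom()
  plan <- mrt_plan(beam_geometry(), prescription_peak_gy = 20, roi = "brain")
  rep <- compute_plan(ph, plan, std_spectrum(), n_histories = 1e5, seed = 12)
  expect_equal(rep$irradiation_time_s * rep$mean_peak_dose_rate / 60,
               rep$prescription_peak_gy, tolerance = 1e-12)
  expect_equal(rep$accumulated_valley_dose_gy,
               rep$mean_valley_dose_rate * rep$irradiation_time_s / 60,
               tolerance = 1e-12)
  expect_equal(rep$mean_pvdr,
               rep$mean_peak_dose_rate / rep$mean_valley_dose_rate,
               tolerance = 1e-12)
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_gt(rep$mean_ctc_um, 400)   # divergence magnifies the period
})

test_that("field-size behaviour: valley rates rise, PVDR falls with field", {
  sp <- std_spectrum()
  ph <- small_pmma(c(30, 30, 16), vox = 2)
  reports <- purrr::map(c(5, 10), function(f) {
    g <- beam_geometry(field_mm = c(f, f))
    ph_t <- tag_beam_roi(ph, g, gap_mm = 4, margin = 0.7)
    plan <- mrt_plan(g, prescription_peak_gy = 20, roi = "beam")
    compute_plan(ph_t, plan, sp, n_histories = 2e5, seed = 31)
  })
  expect_gt(reports[[2]]$mean_valley_dose_rate,
            reports[[1]]$mean_valley_dose_rate)
  expect_lt(reports[[2]]$mean_pvdr, reports[[1]]$mean_pvdr)
  # peak dose rates are approximately field-size independent
  expect_equal(reports[[2]]$mean_peak_dose_rate /
                 reports[[1]]$mean_peak_dose_rate, 1, tolerance = 0.1)
})

test_that("positioning offsets follow the laser-home convention", {
  plan0 <- mrt_plan(beam_geometry(), 20, "brain")
  off0 <- positioning_offsets(plan0)
  expect_equal(unlist(off0), c(dx_mm = 0, dy_mm = 0, rotation_deg = 0))
  plan5 <- mrt_plan(beam_geometry(), 20, "brain", beam_offset_mm = c(5, 0))
  expect_equal(positioning_offsets(plan5)$dx_mm, 5)
  plan60 <- mrt_plan(beam_geometry(), 20, "brain", beam_offset_mm = c(60, 0))
  expect_error(positioning_offsets(plan60), "stage travel")
})

test_that("an ROI outside the beam is refused with its extent named", {
  ph <- small_pmma(c(40, 40, 10), vox = 2)
  g <- beam_geometry(field_mm = c(5, 5))
  ph$roi$all <- array(TRUE, dim(ph$density))
  plan <- mrt_plan(g, 20, roi = "all")
  expect_error(compute_plan(ph, plan, std_spectrum(), n_histories = 1e4,
                            seed = 1),
               "outside the beam")
})

test_that("depth report annotates valley maxima and log-linear peaks", {
  sp <- std_spectrum()
  geom <- beam_geometry()
  ph <- make_slab_phantom(c(40, 40, 60), "pmma", voxel_mm = 2)
  dg <- simulate_photon_dose(ph, geom, sp, 1e6, seed = 17)
  dd <- depth_dose_report(dg, geom, lateral_halfwidth_mm = 8)
  expect_identical(nrow(dd), 30L)
  expect_true(all(c("peak", "valley", "pvdr", "fwhm_um", "ctc_um")
                  %in% names(dd)))
  mx <- attr(dd, "valley_maxima")
  expect_true(tibble::is_tibble(mx))
  # inverse-square-corrected log primary dose is linear with depth (the
  # reconstructed peak additionally flattens as penumbras blur)
  y <- 212 + 4 + dd$depth_mm
  fit <- stats::lm(log(dd$d_primary * (y / 212)^2) ~ dd$depth_mm)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(stats::cor(dd$depth_mm, dd$peak, method = "spearman"), -0.99)
  expect_true(all(diff(dd$ctc_um) > 0))
})

test_that("couch rotation resamples the phantom", {
  ph <- make_mouse_head_phantom()
  rot <- mrtplan:::resample_phantom(ph, c(collimator = 0, couch = 90,
                                          gantry = 0))
  expect_identical(dim(rot$density), dim(ph$density))
  expect_identical(sort(unique(as.vector(rot$material))),
                   sort(unique(as.vector(ph$material))))
  ident <- mrtplan:::resample_phantom(ph, c(collimator = 0, couch = 0,
                                            gantry = 0))
  expect_identical(ident$density, ph$density)
})
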