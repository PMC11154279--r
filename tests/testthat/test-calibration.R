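# focal-spot sigma fitting and film calibration

test_that("sigma is recovered from noiseless synthetic profiles", {
  g <- beam_geometry(focal_spot = focal_spot(0.58))
  meas <- simulate_measured_profiles(g, depths_mm = c(10, 30), noise = 0,
                                     seed = 1)
  fit <- fit_focal_spot_sigma(meas, beam_geometry(focal_spot = focal_spot(1)))
  expect_equal(fit$sigma_mm, 0.58, tolerance = 0.005)
  expect_equal(fit$fwtm_mm, fwtm_from_sigma(fit$sigma_mm))
})

test_that("sigma recovery survives 2% multiplicative noise within 5%", {
  g <- beam_geometry(focal_spot = focal_spot(0.58))
  meas <- simulate_measured_profiles(g, depths_mm = c(10, 25, 40),
                                     noise = 0.02, seed = 42)
  fit <- fit_focal_spot_sigma(meas, beam_geometry())
  expect_equal(fit$sigma_mm, 0.58, tolerance = 0.05 * 0.58)
  expect_equal(signif(fit$fwtm_mm, 2), 2.5)
  td <- tidy(fit)
  expect_identical(td$term, "sigma_mm")
  expect_true(td$conf.low < fit$sigma_mm && fit$sigma_mm < td$conf.high)
})

test_that("the sigma objective is unimodal over the search bracket", {
  g <- beam_geometry(focal_spot = focal_spot(0.58))
  meas <- simulate_measured_profiles(g, depths_mm = 25, noise = 0.01,
                                     seed = 7)
  fit <- fit_focal_spot_sigma(meas, beam_geometry())
  grid <- seq(0.1, 1.5, length.out = 12)
  obj <- vapply(grid, fit$ssr_fun, numeric(1))
  sign_changes <- sum(diff(sign(diff(obj))) != 0)
  expect_lte(sign_changes, 1)
})

test_that("recovery degrades as the injected noise grows", {
  g <- beam_geometry(focal_spot = focal_spot(0.58))
  errs <- vapply(c(0.005, 0.10), function(nz) {
    meas <- simulate_measured_profiles(g, depths_mm = c(15, 35),
                                       noise = nz, seed = 11)
    abs(fit_focal_spot_sigma(meas, beam_geometry())$sigma_mm - 0.58)
  }, numeric(1))
  expect_gte(errs[2], errs[1])
})

test_that("film calibration recovers known parameters exactly", {
  a <- 0.31; b <- 212; c <- 41
  gv <- seq(60, 240, length.out = 6)
  d <- tibble::tibble(gray_value = gv, dose_gy = a + b / (gv + c))
  fit <- fit_film_calibration(d)
  expect_equal(fit$a, a, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_equal(fit$c, c, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-8)
  # inverse consistency at the calibration points
  pred <- apply_film_calibration(fit, gv)
  expect_equal(pred$dose_gy, d$dose_gy, tolerance = 1e-6)
  expect_false(any(pred$extrapolated))
})

test_that("a six-point 0-10 Gy calibration is monotone", {
  set.seed(3)
  gv <- c(230, 180, 140, 110, 85, 65)
  d <- tibble::tibble(gray_value = gv,
                      dose_gy = 0.2 + 600 / (gv + 20) * (1 + rnorm(6, 0, 0.01)))
  d$dose_gy <- pmin(d$dose_gy, 10)
  fit <- fit_film_calibration(d)
  curve <- apply_film_calibration(fit, seq(65, 230, by = 5))$dose_gy
  expect_true(all(diff(curve) < 0))
  g <- glance(fit)
  expect_identical(g$n, 6L)
})

test_that("film application is vectorised and flags extrapolation", {
  gv <- seq(80, 200, length.out = 5)
  d <- tibble::tibble(gray_value = gv, dose_gy = 1 + 300 / (gv + 30))
  fit <- fit_film_calibration(d)
  vec <- apply_film_calibration(fit, gv)$dose_gy
  one <- vapply(gv, function(g) apply_film_calibration(fit, g)$dose_gy,
                numeric(1))
  expect_identical(vec, one)
  expect_warning(out <- apply_film_calibration(fit, c(10, 100)), "clamped")
  expect_identical(out$extrapolated, c(TRUE, FALSE))
})

test_that("degenerate film inputs are rejected", {
  expect_error(fit_film_calibration(
    tibble::tibble(gray_value = c(1, 2, 3), dose_gy = c(1, 2, 3))),
    "at least 4")
  expect_error(fit_film_calibration(
    tibble::tibble(gray_value = rep(5, 5), dose_gy = 1:5)),
    "degenerate|constant")
})
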