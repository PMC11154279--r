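# Calibration of the dose engine: (a) effective focal-spot sigma fitted
# against measured microbeam profiles, (b) radiochromic-film gray-value ->
# dose calibration curve.

#' Simulate measured microbeam profiles
#'
#' Generates synthetic "measured" profiles at given depths with the
#' deterministic profile model and optional multiplicative noise; used for
#' parameter-recovery studies and as a stand-in for film scans.
#'
#' @param geometry A [beam_geometry()]; its `focal_spot` sigma is the ground
#'   truth.
#' @param depths_mm Depths (beyond the collimator plane) of the profile
#'   planes, mm.
#' @param kernel Optional [electron_kernel()].
#' @param noise Multiplicative noise standard deviation (e.g. 0.02 for 2%).
#' @param seed Seed for the noise.
#' @param pitch_um Sampling pitch, micrometres.
#' @param span_periods Periods covered per profile.
#' @param scatter_fraction Flat scatter pedestal as a fraction of the
#'   primary dose.
#' @return A tibble with columns `label`, `depth_mm`, `position_um`,
#'   `value`.
#' @export
simulate_measured_profiles <- function(geometry, depths_mm, kernel = NULL,
                                       noise = 0, seed = 1, pitch_um = 2,
                                       span_periods = 5,
                                       scatter_fraction = 0.1) {
  set.seed(as.integer(seed))
  purrr::map_dfr(depths_mm, function(dep) {
    pr <- reconstruct_profile(1, scatter_fraction, geometry, kernel,
                              y_mm = geometry$sd_mm + dep,
                              pitch_um = pitch_um,
                              span_periods = span_periods)
    val <- pr$dose
    if (noise > 0) val <- val * (1 + rnorm(length(val), sd = noise))
    tibble(label = sprintf("depth_%gmm", dep), depth_mm = dep,
           position_um = pr$position_um, value = val)
  })
}

#' Fit the effective focal-spot width against measured profiles
#'
#' Bounded 1D least squares over the focal-spot standard deviation: for each
#' candidate sigma the deterministic profile model is evaluated at each
#' measured profile's depth and sampling positions, an amplitude scale is
#' fitted per profile (decoupling profile shape from absolute dose
#' calibration), and the summed squared residuals are minimised with
#' [stats::optimize()].  A curvature-based approximate 95% confidence
#' interval is reported.
#'
#' @param measured A tibble as produced by [simulate_measured_profiles()]
#'   (columns `label`, `depth_mm`, `position_um`, `value`), or a list of
#'   such tibbles.
#' @param geometry A [beam_geometry()]; all parameters except the focal-spot
#'   sigma are held fixed.
#' @param kernel Optional [electron_kernel()] used in the model profiles.
#' @param bounds Search bracket for sigma, mm.
#' @param scatter_fraction Scatter pedestal fraction assumed in the model
#'   profiles.
#' @return An object of class `sigma_fit` with elements `sigma_mm`,
#'   `conf_low`, `conf_high`, `objective`, `fwtm_mm`, `scan` (the objective
#'   trace).  Supports [tidy()] and [glance()].
#' @export
fit_focal_spot_sigma <- function(measured, geometry, kernel = NULL,
                                 bounds = c(0.05, 3),
                                 scatter_fraction = 0.1) {
  if (is.data.frame(measured)) {
    measured <- split(measured, measured$label)
  }
  if (!length(measured)) abort("at least one measured profile is required")
  for (m in measured) {
    if (is.unsorted(m$position_um, strictly = TRUE)) {
      abort("profile positions must be strictly increasing")
    }
  }
  ssr <- function(sigma) {
    g <- geometry
    g$focal_spot <- focal_spot(sigma)
    sum(vapply(measured, function(m) {
      pr <- reconstruct_profile(1, scatter_fraction, g, kernel,
                                y_mm = geometry$sd_mm + m$depth_mm[1],
                                pitch_um = min(2, diff(m$position_um[1:2])),
                                span_periods = ceiling(
                                  diff(range(m$position_um)) / 1000 /
                                    (geometry$collimator$ctc_um / 1000)) + 2)
      mod <- approx(pr$position_um, pr$dose, xout = m$position_um,
                    rule = 2)$y
      a <- sum(mod * m$value) / sum(mod^2)
      sum((m$value - a * mod)^2)
    }, numeric(1)))
  }
  opt <- optimize(ssr, interval = bounds, tol = 1e-4)
  sigma_hat <- opt$minimum
  if (min(abs(sigma_hat - bounds)) < 1e-3) {
    abort("sigma fit did not converge inside the search bracket")
  }
  # curvature-based interval: SSR approx quadratic near the minimum
  h <- max(1e-3, sigma_hat * 0.02)
  f0 <- opt$objective
  fp <- ssr(sigma_hat + h); fm <- ssr(sigma_hat - h)
  curv <- (fp + fm - 2 * f0) / h^2
  n_obs <- sum(vapply(measured, nrow, numeric(1)))
  sigma2_res <- f0 / max(n_obs - 2, 1)
  se <- if (curv > 0) sqrt(2 * sigma2_res / curv) else NA_real_
  scan_sigma <- seq(bounds[1], bounds[2], length.out = 25)
  structure(list(sigma_mm = sigma_hat,
                 conf_low = sigma_hat - 1.96 * se,
                 conf_high = sigma_hat + 1.96 * se,
                 se = se, objective = f0, n_profiles = length(measured),
                 n_obs = n_obs, fwtm_mm = fwtm_from_sigma(sigma_hat),
                 ssr_fun = ssr, bounds = bounds),
            class = "sigma_fit")
}

#' @export
print.sigma_fit <- function(x, ...) {
  cat(sprintf(
    "<sigma_fit> sigma = %.4f mm [%.4f, %.4f] | effective focal spot (FWTM) = %.2f mm\n",
    x$sigma_mm, x$conf_low, x$conf_high, x$fwtm_mm))
  invisible(x)
}

#' Fit the radiochromic-film calibration curve
#'
#' Nonlinear least squares of the rational dose-response
#' `D(gv) = a + b / (gv + c)` to film calibration points (dose in Gy,
#' scanner gray value), the standard form for radiochromic film where the
#' gray value decreases with dose.
#'
#' @param data A data frame with columns `dose_gy` and `gray_value`
#'   (>= 4 points), doses within (0, 10) Gy.
#' @param start Optional named list of starting values for `a`, `b`, `c`.
#' @return An object of class `film_calibration` with the fit parameters,
#'   RMS residual and fitted gray-value range.  Supports [tidy()],
#'   [glance()] and [apply_film_calibration()].
#' @export
#' @examples
#' d <- tibble::tibble(dose_gy = c(0.5, 1, 2, 4, 6, 9))
#' d$gray_value <- 200 / (d$dose_gy + 0.4) + 30
#' fit <- fit_film_calibration(d)
#' glance(fit)
fit_film_calibration <- function(data, start = NULL) {
  if (nrow(data) < 4) abort("at least 4 calibration points are required")
  if (any(data$dose_gy <= 0 | data$dose_gy > 10)) {
    abort("calibration doses must lie in (0, 10] Gy")
  }
  if (diff(range(data$gray_value)) < 1e-9) {
    abort("degenerate calibration: gray values are constant")
  }
  if (is.null(start)) {
    # crude initialisation from the two extreme points
    gv <- data$gray_value; d <- data$dose_gy
    c0 <- -min(gv) + diff(range(gv)) * 0.5
    b0 <- (max(d) - min(d)) /
      (1 / (min(gv) + c0) - 1 / (max(gv) + c0))
    a0 <- mean(d - b0 / (gv + c0))
    start <- list(a = a0, b = b0, c = c0)
  }
  fit <- minpack.lm::nlsLM(dose_gy ~ a + b / (gray_value + c),
                           data = data, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- coef(fit)
  res <- stats::resid(fit)
  structure(list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                 rms_residual = sqrt(mean(res^2)),
                 gray_range = range(data$gray_value),
                 dose_range = range(data$dose_gy),
                 n = nrow(data), fit = fit),
            class = "film_calibration")
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf(
    "<film_calibration> D(gv) = %.4g + %.4g/(gv + %.4g) | RMS %.3g Gy | gv in [%g, %g]\n",
    x$a, x$b, x$c, x$rms_residual, x$gray_range[1], x$gray_range[2]))
  invisible(x)
}

#' Convert film gray values to dose
#'
#' Evaluates a fitted [fit_film_calibration()] curve.  Gray values outside
#' the fitted range are clamped to it and flagged.
#'
#' @param calibration A `film_calibration`.
#' @param gray_values Numeric gray values.
#' @return A tibble with columns `gray_value`, `dose_gy`, and
#'   `extrapolated` (TRUE where the input fell outside the fitted range and
#'   was clamped).
#' @export
apply_film_calibration <- function(calibration, gray_values) {
  lo <- calibration$gray_range[1]; hi <- calibration$gray_range[2]
  out_of_range <- gray_values < lo | gray_values > hi
  if (any(out_of_range)) {
    warn(sprintf("%d gray value(s) outside the fitted range were clamped",
                 sum(out_of_range)))
  }
  gv <- pmin(pmax(gray_values, lo), hi)
  tibble(gray_value = gray_values,
         dose_gy = calibration$a + calibration$b / (gv + calibration$c),
         extrapolated = out_of_range)
}
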