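# broom-style tidiers for the fitted objects

#' Tidy a focal-spot sigma fit
#'
#' @param x A `sigma_fit` from [fit_focal_spot_sigma()].
#' @param ... Unused.
#' @return One row per parameter with estimate, standard error and
#'   confidence bounds.
#' @export
tidy.sigma_fit <- function(x, ...) {
  tibble(term = "sigma_mm", estimate = x$sigma_mm, std.error = x$se,
         conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @rdname tidy.sigma_fit
#' @export
glance.sigma_fit <- function(x, ...) {
  tibble(sigma_mm = x$sigma_mm, fwtm_mm = x$fwtm_mm, objective = x$objective,
         n_profiles = x$n_profiles, n_obs = x$n_obs)
}

#' Tidy a film calibration fit
#'
#' @param x A `film_calibration` from [fit_film_calibration()].
#' @param ... Unused.
#' @return One row per fit parameter of `D(gv) = a + b/(gv + c)`.
#' @export
tidy.film_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' @rdname tidy.film_calibration
#' @export
glance.film_calibration <- function(x, ...) {
  tibble(a = x$a, b = x$b, c = x$c, rms_residual = x$rms_residual,
         n = x$n, gray_min = x$gray_range[1], gray_max = x$gray_range[2])
}
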