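# shared fixtures: small geometries and synthetic profiles used across tests

toy_geometry <- function(sigma_mm = 0.3, field_mm = 2, leakage = NULL) {
  beam_geometry(field_mm = c(field_mm, field_mm),
                focal_spot = focal_spot(sigma_mm),
                collimator = collimator(leakage = leakage))
}

std_spectrum <- function() {
  if (is.null(.fixture_env$spectrum)) {
    .fixture_env$spectrum <- generate_spectrum(225, 1)
  }
  .fixture_env$spectrum
}

small_pmma <- function(dims = c(30, 30, 20), vox = 2) {
  make_slab_phantom(dims, "pmma", voxel_mm = vox)
}

# ideal rectangular microbeam array profile (analytic fixture)
rect_array_profile <- function(width_um = 100, period_um = 400,
                               high = 10, low = 2, n_periods = 5,
                               pitch_um = 1) {
  x <- seq(-n_periods / 2 * period_um, n_periods / 2 * period_um,
           by = pitch_um)
  d <- x - round(x / period_um) * period_um
  tibble::tibble(position_um = x,
                 dose = ifelse(abs(d) <= width_um / 2, high, low))
}

# period mean computed independently of the package helper
own_period_mean <- function(position_um, values, period_um) {
  keep <- position_um >= -period_um / 2 & position_um < period_um / 2
  mean(values[keep])
}

.fixture_env <- new.env()
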