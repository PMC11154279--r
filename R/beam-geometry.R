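#' Focal spot model
#'
#' The X-ray tube focal spot is modelled as a 1D Gaussian intensity profile
#' of standard deviation `sigma_mm` in the lateral direction; `sigma_mm = 0`
#' denotes an ideal point source.
#'
#' @param sigma_mm Standard deviation of the Gaussian focal-spot profile, mm.
#' @return An object of class `focal_spot`.
#' @export
#' @examples
#' fs <- focal_spot(0.58)
#' fwtm_from_sigma(fs$sigma_mm)
focal_spot <- function(sigma_mm) {
  assert_scalar_num(sigma_mm, "sigma_mm", 0, Inf)
  structure(list(sigma_mm = sigma_mm), class = "focal_spot")
}

#' Multislit collimator model
#'
#' Periodic array of slits in a thick absorber.  Transmittance is 1 inside a
#' slit, the septum leakage value inside a septum, and 0 outside the field
#' aperture.  Unless overridden, the leakage is computed from the bundled
#' septum-material attenuation table at the spectrum's mean energy when the
#' transmittance is evaluated.
#'
#' @param slit_um Slit opening in micrometres.
#' @param ctc_um Center-to-center distance (array period) in micrometres.
#' @param septum_mm Septum (absorber) thickness in mm.
#' @param septum_material Septum material name (see [list_materials()]).
#' @param leakage Optional constant septum transmittance in \[0, 1) that
#'   overrides the computed value.
#' @return An object of class `collimator`.
#' @export
collimator <- function(slit_um = 30, ctc_um = 400, septum_mm = 7,
                       septum_material = "tungsten", leakage = NULL) {
  assert_scalar_num(slit_um, "slit_um", 0, Inf, allow_equal = FALSE)
  assert_scalar_num(ctc_um, "ctc_um", slit_um, Inf, allow_equal = FALSE)
  if (!is.null(leakage)) assert_scalar_num(leakage, "leakage", 0, 1 - 1e-12)
  structure(list(slit_um = slit_um, ctc_um = ctc_um, septum_mm = septum_mm,
                 septum_material = septum_material, leakage = leakage),
            class = "collimator")
}

#' Divergent-beam geometry
#'
#' Bundles the source-to-collimator distance, field size (defined at the
#' collimator plane), focal spot and collimator into the ray model used by
#' the dose engine.  The collimator tilt is recorded as metadata only; its
#' optical effect (a reduced effective focal spot) is absorbed into the
#' calibrated `sigma_mm`.
#'
#' @param sd_mm Source-to-collimator distance, mm.
#' @param field_mm Field size at the collimator plane, mm (length 1 or 2).
#' @param tilt_deg Collimator tilt around the source, degrees (metadata).
#' @param focal_spot A [focal_spot()].
#' @param collimator A [collimator()].
#' @return An object of class `beam_geometry`.
#' @export
#' @examples
#' geom <- beam_geometry()
#' magnification(geom$sd_mm, 6)
beam_geometry <- function(sd_mm = 212, field_mm = c(20, 20), tilt_deg = 8,
                          focal_spot = mrtplan::focal_spot(0.58),
                          collimator = mrtplan::collimator()) {
  assert_scalar_num(sd_mm, "sd_mm", 0, Inf, allow_equal = FALSE)
  if (length(field_mm) == 1L) field_mm <- rep(field_mm, 2L)
  if (any(field_mm <= 0)) abort("`field_mm` must be positive")
  structure(list(sd_mm = sd_mm, field_mm = field_mm, tilt_deg = tilt_deg,
                 focal_spot = focal_spot, collimator = collimator),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf(
    "<beam_geometry> sd %g mm | field %g x %g mm^2 | slit %g um | ctc %g um | sigma %g mm\n",
    x$sd_mm, x$field_mm[1], x$field_mm[2], x$collimator$slit_um,
    x$collimator$ctc_um, x$focal_spot$sigma_mm))
  invisible(x)
}

#' Full width at one tenth of maximum of a Gaussian
#'
#' Converts the Gaussian focal-spot standard deviation into the focal spot
#' size defined (per the X-ray tube norm convention) as the full width of the
#' intensity profile at 10% of its maximum: \eqn{d = \sigma\sqrt{8\ln 10}}.
#'
#' @param sigma_mm Gaussian standard deviation, mm (non-negative).
#' @return Full width at tenth maximum, mm.
#' @export
#' @examples
#' fwtm_from_sigma(0.58) # ~2.5 mm effective focal spot
fwtm_from_sigma <- function(sigma_mm) {
  if (any(sigma_mm < 0)) abort("`sigma_mm` must be non-negative")
  sigma_mm * sqrt(8 * log(10))
}

#' Geometric magnification beyond the collimator plane
#'
#' By the intersecting-lines theorem, a periodic structure at the collimator
#' plane (distance `sd_mm` from the source) is projected onto a plane
#' `delta_mm` further downstream with magnification `(sd + delta)/sd`.
#'
#' @param sd_mm Source-to-collimator distance, mm (> 0).
#' @param delta_mm Distance beyond the collimator plane, mm (>= -sd_mm).
#' @return Dimensionless magnification factor.
#' @export
#' @examples
#' magnification(212, 6) # ~1.03 across a 6 mm thick target
magnification <- function(sd_mm, delta_mm) {
  if (any(sd_mm <= 0)) abort("`sd_mm` must be positive")
  if (any(delta_mm < -sd_mm)) abort("`delta_mm` must be >= -sd_mm")
  (sd_mm + delta_mm) / sd_mm
}

#' Focal-spot intensity profile
#'
#' Normalised Gaussian intensity density of the focal spot evaluated at
#' source-plane positions `x_mm`.
#'
#' @param x_mm Lateral source-plane positions, mm.
#' @param focal_spot A [focal_spot()]; `sigma_mm` must be positive (a point
#'   source has no density and callers use the pinhole code path instead).
#' @return Intensity density values, 1/mm.
#' @export
source_profile <- function(x_mm, focal_spot) {
  s <- focal_spot$sigma_mm
  if (s <= 0) {
    abort("point source (sigma = 0): use the pinhole code path, not a density")
  }
  stats::dnorm(x_mm, sd = s)
}

# effective energy used for septum leakage: fluence-weighted mean
collimator_leakage <- function(collimator, energy_kev) {
  if (!is.null(collimator$leakage)) return(collimator$leakage)
  mu <- attenuation_coefficient(collimator$septum_material, energy_kev)
  exp(-mu * collimator$septum_mm)
}

#' Collimator transmittance profile
#'
#' Transmittance as a function of position in the collimator plane: 1 inside
#' a slit, the septum leakage inside a septum, 0 outside the field aperture.
#' Slits are centred on multiples of the center-to-center distance; the
#' number of slits is derived from the field size.
#'
#' @param x_mm Collimator-plane lateral positions, mm.
#' @param collimator A [collimator()].
#' @param field_mm Field width at the collimator plane, mm.
#' @param energy_kev Effective photon energy used to evaluate septum leakage
#'   from the bundled attenuation table (ignored when the collimator carries
#'   an explicit leakage override).
#' @return Transmittance values in \[0, 1\].
#' @export
collimator_transmittance <- function(x_mm, collimator, field_mm = 20,
                                     energy_kev = 100) {
  leak <- collimator_leakage(collimator, energy_kev)
  ctc <- collimator$ctc_um / 1000
  slit <- collimator$slit_um / 1000
  in_field <- abs(x_mm) <= field_mm / 2
  # distance to the nearest slit centre (slit centres at k * ctc)
  d <- abs(x_mm - round(x_mm / ctc) * ctc)
  out <- ifelse(d <= slit / 2, 1, leak)
  out[!in_field] <- 0
  out
}

# slit centres inside the aperture
slit_centers_mm <- function(collimator, field_mm) {
  ctc <- collimator$ctc_um / 1000
  kmax <- floor((field_mm / 2) / ctc)
  (-kmax:kmax) * ctc
}

# area-weighted (anti-aliased) transmittance sample: each pixel of width
# `pitch_mm` carries the slit coverage fraction, so the sampled pattern
# integrates like the continuous one (pixel-edge quantisation would
# otherwise alias into the convolution path)
collimator_transmittance_aa <- function(x_mm, collimator, field_mm,
                                        energy_kev = 100, pitch_mm) {
  leak <- collimator_leakage(collimator, energy_kev)
  ctc <- collimator$ctc_um / 1000
  h <- collimator$slit_um / 2000                     # slit half width
  d <- x_mm - round(x_mm / ctc) * ctc                # offset to slit centre
  overlap <- pmax(0, pmin(d + pitch_mm / 2, h) - pmax(d - pitch_mm / 2, -h))
  cov <- pmin(overlap / pitch_mm, 1)
  ap <- pmax(0, pmin(x_mm + pitch_mm / 2, field_mm / 2) -
               pmax(x_mm - pitch_mm / 2, -field_mm / 2)) / pitch_mm
  (leak + (1 - leak) * cov) * ap
}

#' Primary fluence pattern at depth
#'
#' The lateral pattern of primary photon fluence at a plane a distance
#' `y_mm` from the source is the focal-spot intensity integrated against the
#' collimator transmittance along each ray.  Two code paths are provided: a
#' direct numerical quadrature of that integral, and the fast equivalent form
#' in which the transmittance, magnified onto the target plane, is convolved
#' with the focal-spot profile rescaled by the penumbra factor
#' `(y - sd)/sd`.  The pattern is normalised to unit mean over one projected
#' period, so that a voxel's period-averaged primary dose multiplies it
#' directly.
#'
#' @param geometry A [beam_geometry()].
#' @param y_mm Source-to-plane distance, mm (>= `sd_mm`).
#' @param x_range_mm Half-range of the lateral grid, mm; defaults to the
#'   projected field half-width plus a margin.
#' @param pitch_um Lateral sampling pitch in micrometres (<= 1 um pitch is
#'   recommended; the default is 1).
#' @param method `"convolution"` (fast path) or `"quadrature"` (direct
#'   integral; an independent oracle for the fast path).
#' @param energy_kev Effective energy for septum leakage.
#' @return A tibble with columns `position_um` (target-plane coordinate) and
#'   `relative_fluence` (unit period mean), with attributes `y_mm` and
#'   `period_um` (projected center-to-center distance).
#' @export
#' @examples
#' geom <- beam_geometry(focal_spot = focal_spot(0.2))
#' pat <- fluence_pattern(geom, y_mm = 230, x_range_mm = 1)
fluence_pattern <- function(geometry, y_mm, x_range_mm = NULL, pitch_um = 1,
                            method = c("convolution", "quadrature"),
                            energy_kev = 100) {
  method <- match.arg(method)
  sd_mm <- geometry$sd_mm
  if (y_mm < sd_mm) abort("`y_mm` must be at or beyond the collimator plane")
  mag <- y_mm / sd_mm
  col <- geometry$collimator
  field <- geometry$field_mm[1]
  if (is.null(x_range_mm)) x_range_mm <- field / 2 * mag + 2
  pitch_mm <- pitch_um / 1000
  x <- seq(-x_range_mm, x_range_mm, by = pitch_mm)
  sigma <- geometry$focal_spot$sigma_mm
  sigma_proj <- sigma * (y_mm - sd_mm) / sd_mm

  if (method == "quadrature" && sigma > 0 && y_mm > sd_mm) {
    # direct evaluation of theta(x) = int f_s(x') f_c(x''(x, x')) dx' with
    # x''(x, x') = x' (1 - sd/y) + x sd/y.  Substituting u = x'' turns the
    # integral into a Gaussian (mean x sd/y, width sigma |1 - y/sd| sd/y)
    # weighted average of the piecewise-constant transmittance, which is an
    # exact sum of normal-CDF differences over the slits.
    kap <- abs(1 - sd_mm / y_mm)
    s_u <- sigma * kap
    mu <- x * (sd_mm / y_mm)
    leak <- collimator_leakage(col, energy_kev)
    centers <- slit_centers_mm(col, field)
    h <- col$slit_um / 2000
    th <- leak * (stats::pnorm((field / 2 - mu) / s_u) -
                    stats::pnorm((-field / 2 - mu) / s_u))
    for (cc in centers) {
      a <- max(cc - h, -field / 2); b <- min(cc + h, field / 2)
      th <- th + (1 - leak) *
        (stats::pnorm((b - mu) / s_u) - stats::pnorm((a - mu) / s_u))
    }
  } else {
    # magnified transmittance (the collimator-plane coordinate is x sd/y)
    th <- collimator_transmittance_aa(x / mag, col, field, energy_kev,
                                      pitch_mm = pitch_mm / mag)
    if (sigma_proj > pitch_mm / 10) {
      half_k <- max(3L, ceiling(6 * sigma_proj / pitch_mm))
      xk <- (-half_k:half_k) * pitch_mm
      k <- stats::pnorm((xk + pitch_mm / 2) / sigma_proj) -
        stats::pnorm((xk - pitch_mm / 2) / sigma_proj)
      k <- k / sum(k)
      th <- conv_same(th, k)
    }
  }

  period_mm <- col$ctc_um / 1000 * mag
  th <- th / period_mean(x, th, period_mm)
  out <- tibble(position_um = x * 1000, relative_fluence = th)
  structure(out, class = c("fluence_pattern", class(out)),
            y_mm = y_mm, period_um = period_mm * 1000)
}

# mean of a pattern over the central projected period (slit centred at 0)
period_mean <- function(x_mm, values, period_mm) {
  keep <- x_mm >= -period_mm / 2 & x_mm < period_mm / 2
  mean(values[keep])
}

#' Depth at which adjacent microbeam penumbras first overlap
#'
#' With increasing distance beyond the collimator the projected slit width
#' grows with the beam magnification while the focal-spot penumbra grows in
#' proportion to the distance from the collimator.  This returns the distance
#' beyond the collimator plane at which the projected beam width (magnified
#' slit plus full-width-at-tenth-maximum penumbra) first equals the projected
#' center-to-center distance, i.e. the closed-form solution of
#' `slit * y/sd + d * (y - sd)/sd = ctc * y/sd` with `d` the focal-spot FWTM.
#'
#' @param geometry A [beam_geometry()].
#' @return Distance beyond the collimator plane in mm, or `Inf` when the
#'   penumbras never overlap (focal-spot FWTM not exceeding `ctc - slit`).
#' @export
#' @examples
#' penumbra_overlap_depth(beam_geometry())
penumbra_overlap_depth <- function(geometry) {
  d <- fwtm_from_sigma(geometry$focal_spot$sigma_mm)
  ctc <- geometry$collimator$ctc_um / 1000
  slit <- geometry$collimator$slit_um / 1000
  if (d <= ctc - slit) return(Inf)
  d * geometry$sd_mm / (d - ctc + slit) - geometry$sd_mm
}
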