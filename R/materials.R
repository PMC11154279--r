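#' Materials database bundled with the package
#'
#' The package ships energy-dependent mass attenuation (\eqn{\mu/\rho}) and
#' mass energy-absorption (\eqn{\mu_{en}/\rho}) tables for the materials a
#' kilovoltage dose engine needs: air, lung, water, soft tissue, PMMA,
#' cortical bone, aluminium, tungsten and lead.  Tables cover 10-300 keV and
#' are interpolated log-log.
#'
#' @return A tibble with one row per material: `name`, nominal
#'   `density_g_cm3`, and the mean ratio of atomic number to mass number
#'   `z_over_a` used to compute electron densities.
#' @export
#' @examples
#' list_materials()
list_materials <- function() {
  db <- materials_db()
  tibble(name = db$meta$name,
         density_g_cm3 = db$meta$density_g_cm3,
         z_over_a = db$meta$z_over_a)
}

materials_db <- function() {
  if (!is.null(the$materials)) return(the$materials)
  dir <- system.file("extdata", package = "mrtplan")
  meta <- read.csv(file.path(dir, "materials.csv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  tables <- lapply(seq_len(nrow(meta)), function(i) {
    read.csv(file.path(dir, "attenuation", meta$table[i]),
             comment.char = "#", stringsAsFactors = FALSE)
  })
  names(tables) <- meta$name
  the$materials <- list(meta = meta, tables = tables)
  the$materials
}

material_meta <- function(material) {
  db <- materials_db()
  i <- match(material, db$meta$name)
  if (is.na(i)) {
    abort(sprintf("unknown material '%s'; see list_materials()", material))
  }
  list(meta = db$meta[i, ], table = db$tables[[i]])
}

#' Mass attenuation and energy-absorption coefficients
#'
#' Log-log interpolation of the bundled cross-section tables.
#'
#' @param material Material name (see [list_materials()]).
#' @param energy_kev Photon energies in keV (vectorised), within 10-300 keV.
#' @param kind `"mu"` for the mass attenuation coefficient, `"mu_en"` for the
#'   mass energy-absorption coefficient.
#' @return Coefficient values in cm^2/g.
#' @export
#' @examples
#' mass_attenuation("pmma", 100)
mass_attenuation <- function(material, energy_kev, kind = c("mu", "mu_en")) {
  kind <- match.arg(kind)
  tb <- material_meta(material)$table
  col <- if (kind == "mu") tb$mu_over_rho_cm2_g else tb$mu_en_over_rho_cm2_g
  loglog_interp(energy_kev, tb$energy_kev, col)
}

#' Linear attenuation coefficient
#'
#' @inheritParams mass_attenuation
#' @param density Mass density in g/cm^3; defaults to the material's nominal
#'   density.
#' @return Linear attenuation coefficient in 1/mm.
#' @export
#' @examples
#' attenuation_coefficient("water", 60)
attenuation_coefficient <- function(material, energy_kev, density = NULL) {
  mm <- material_meta(material)
  density <- density %||% mm$meta$density_g_cm3
  # cm^2/g * g/cm^3 = 1/cm; /10 -> 1/mm
  mass_attenuation(material, energy_kev) * density / 10
}

# --- Klein-Nishina ----------------------------------------------------------

ELECTRON_REST_KEV <- 510.99895
# classical electron radius squared in barn (1 barn = 1e-24 cm^2)
RE2_BARN <- 0.0794098
AVOGADRO <- 6.02214076e23

# total Klein-Nishina cross-section per electron, barn
kn_total_barn <- function(energy_kev) {
  a <- energy_kev / ELECTRON_REST_KEV
  2 * pi * RE2_BARN * (
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
      log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
  )
}

# Klein-Nishina incoherent mass attenuation coefficient, cm^2/g
kn_mu_over_rho <- function(material, energy_kev) {
  z_over_a <- material_meta(material)$meta$z_over_a
  kn_total_barn(energy_kev) * 1e-24 * AVOGADRO * z_over_a
}

# mean fraction of the photon energy transferred to the Compton electron,
# computed by quadrature over the Klein-Nishina angular distribution
kn_mean_transfer_fraction <- function(energy_kev) {
  vapply(energy_kev, function(E) {
    a <- E / ELECTRON_REST_KEV
    ct <- seq(-1, 1, length.out = 721)
    r <- 1 / (1 + a * (1 - ct))            # E'/E at cos(theta) = ct
    dsdct <- r^2 * (r + 1 / r - (1 - ct^2))  # unnormalised KN dsigma/dcos
    sum(dsdct * (1 - r)) / sum(dsdct)
  }, numeric(1))
}

# --- X-ray tube spectrum ----------------------------------------------------

#' Model a filtered kilovoltage X-ray tube spectrum
#'
#' Semi-empirical tube spectrum: a Kramers bremsstrahlung continuum with
#' intensity (energy fluence) proportional to `(kvp - E)` -- equivalently
#' photon fluence proportional to `(kvp - E)/E` -- plus the tungsten K
#' characteristic lines when the tube potential exceeds the K-shell binding
#' energy, hardened by aluminium filtration via Beer-Lambert and renormalised
#' to unit total fluence.  A measured spectrum can be supplied instead as a
#' two-column table via `table`.
#'
#' @param kvp Tube potential in kV (40-300).
#' @param filtration_mm_al Aluminium filtration thickness in mm.
#' @param bin_kev Energy bin width in keV.
#' @param characteristic_fraction Fraction of the unfiltered photon fluence
#'   carried by the tungsten K lines (before filtration).
#' @param table Optional data frame with columns `energy_kev` and `fluence`
#'   that bypasses the model (filtration is still applied).
#' @return A tibble of class `xray_spectrum` with columns `energy_kev` and
#'   `fluence` (normalised to sum 1), carrying `kvp` and `filtration_mm_al`
#'   attributes.
#' @export
#' @examples
#' sp <- generate_spectrum(225, filtration_mm_al = 1)
#' spectrum_mean_energy(sp)
generate_spectrum <- function(kvp, filtration_mm_al = 1, bin_kev = 1,
                              characteristic_fraction = 0.08, table = NULL) {
  assert_scalar_num(kvp, "kvp", 40, 300)
  assert_scalar_num(filtration_mm_al, "filtration_mm_al", 0, Inf)
  if (is.null(table)) {
    e <- seq(10, kvp, by = bin_kev)
    # Kramers: intensity ~ (kvp - E), photon fluence ~ (kvp - E)/E
    fl <- pmax(kvp - e, 0) / e
    fl <- fl / sum(fl)
    # tungsten K lines (Kalpha2, Kalpha1, Kbeta1, Kbeta2)
    k_edge <- 69.525
    if (kvp > k_edge) {
      lines <- data.frame(e = c(57.98, 59.32, 67.24, 69.07),
                          w = c(58, 100, 22, 5))
      idx <- vapply(lines$e, function(le) which.min(abs(e - le)), integer(1))
      add <- characteristic_fraction * lines$w / sum(lines$w)
      fl[idx] <- fl[idx] + add
    }
  } else {
    e <- table$energy_kev
    fl <- table$fluence
    if (any(fl < 0)) abort("supplied spectrum has negative fluence")
  }
  if (filtration_mm_al > 0) {
    fl <- fl * exp(-attenuation_coefficient("aluminium", e) * filtration_mm_al)
  }
  out <- tibble(energy_kev = e, fluence = fl / sum(fl))
  structure(out, class = c("xray_spectrum", class(out)),
            kvp = kvp, filtration_mm_al = filtration_mm_al)
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param spectrum An `xray_spectrum` (or any table with `energy_kev` and
#'   `fluence` columns).
#' @return Mean photon energy in keV.
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$energy_kev * spectrum$fluence) / sum(spectrum$fluence)
}

# --- Hounsfield unit mapping ------------------------------------------------

# segment boundaries and density ramps of the 4-class CT conversion
HU_BOUNDS <- c(air = -850, soft = -100, bone = 120)

#' Convert Hounsfield units to material class and density
#'
#' Standard four-segment scheme: air below -850 HU, lung-like tissue to
#' -100 HU, soft tissue to 120 HU, bone above.  Densities follow a
#' piecewise-linear ramp (`1 + HU/1000` g/cm^3 below the bone threshold,
#' a shallower ramp above it), continuous inside each segment.  Inputs
#' outside the CT range \[-1024, 3071\] are clamped with a warning.
#'
#' @param hu Numeric vector of Hounsfield units.
#' @return A tibble with columns `hu`, `material`, `density_g_cm3`.
#' @export
#' @examples
#' hu_to_material(c(-1000, 0, 500))
hu_to_material <- function(hu) {
  if (any(hu < -1024 | hu > 3071)) {
    warn("Hounsfield values outside [-1024, 3071] were clamped")
    hu <- pmin(pmax(hu, -1024), 3071)
  }
  material <- dplyr::case_when(
    hu < HU_BOUNDS[["air"]] ~ "air",
    hu < HU_BOUNDS[["soft"]] ~ "lung",
    hu < HU_BOUNDS[["bone"]] ~ "soft_tissue",
    TRUE ~ "bone_cortical"
  )
  density <- dplyr::case_when(
    material == "air" ~ 0.0012,
    material == "bone_cortical" ~ 1.12 + (hu - HU_BOUNDS[["bone"]]) * 5e-4,
    TRUE ~ pmax(1 + hu / 1000, 0.0012)
  )
  tibble(hu = hu, material = material, density_g_cm3 = density)
}

# inverse of hu_to_material on its image; used for the phantom round trip
material_to_hu <- function(material, density) {
  dplyr::case_when(
    material == "air" ~ -1000,
    material == "bone_cortical" ~ HU_BOUNDS[["bone"]] + (density - 1.12) / 5e-4,
    TRUE ~ (density - 1) * 1000
  )
}
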