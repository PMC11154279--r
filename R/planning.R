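# End-to-end treatment planning: run the two dose stages, aggregate ROI
# statistics, derive the irradiation time for a prescribed peak dose, and
# report positioning parameters.

# machine output calibration: photon histories per minute of beam-on time
# and per mm^2 of field aperture at the reference tube settings (larger
# fields admit proportionally more photons).  A single scalar fixed once
# against the measured mean peak dose rate in the reference treatment
# situation (2.3 Gy/min in the brain target under the 20 x 20 mm^2 field).
DEFAULT_OUTPUT_HIST_PER_MIN_MM2 <- 2.25e11

#' Define a microbeam treatment plan
#'
#' @param geometry A [beam_geometry()].
#' @param prescription_peak_gy Prescribed peak dose in the target, Gy.
#' @param roi Name of the phantom ROI to target (e.g. `"brain"`), or a
#'   logical mask array.
#' @param isocenter_mm Reference-point position (x, y, z), mm; the engraved
#'   mark on the animal bed by convention.
#' @param beam_offset_mm Lateral beam shift (x, y) relative to the
#'   isocenter, mm.
#' @param angles_deg Named collimator/couch/gantry rotations, degrees.
#' @param gap_mm Collimator-to-phantom distance, mm.
#' @param output_hist_per_min_mm2 Machine output calibration: histories per
#'   minute of beam-on time and per mm^2 of field aperture (converts
#'   per-history dose to dose rate; scales with field area).
#' @return An object of class `mrt_plan`.
#' @export
mrt_plan <- function(geometry = beam_geometry(), prescription_peak_gy = 20,
                     roi = "brain", isocenter_mm = c(0, 0, 0),
                     beam_offset_mm = c(0, 0),
                     angles_deg = c(collimator = 0, couch = 0, gantry = 0),
                     gap_mm = 4,
                     output_hist_per_min_mm2 = DEFAULT_OUTPUT_HIST_PER_MIN_MM2) {
  if (prescription_peak_gy <= 0) abort("prescription must be positive")
  structure(list(geometry = geometry,
                 prescription_peak_gy = prescription_peak_gy,
                 roi = roi, isocenter_mm = isocenter_mm,
                 beam_offset_mm = beam_offset_mm, angles_deg = angles_deg,
                 gap_mm = gap_mm,
                 output_hist_per_min_mm2 = output_hist_per_min_mm2),
            class = "mrt_plan")
}

#' Irradiation time for a prescribed peak dose
#'
#' @param prescription_gy Prescribed peak dose, Gy.
#' @param peak_rate_gy_min Mean peak dose rate in the target, Gy/min.
#' @return Irradiation time in seconds (full precision; round for display).
#' @export
#' @examples
#' irradiation_time_s(20, 2.3) # ~522 s
irradiation_time_s <- function(prescription_gy, peak_rate_gy_min) {
  if (any(peak_rate_gy_min <= 0)) abort("peak dose rate must be positive")
  prescription_gy / peak_rate_gy_min * 60
}

#' Valley dose accumulated over an irradiation
#'
#' @param valley_rate_gy_min Mean valley dose rate, Gy/min.
#' @param time_s Irradiation time, s.
#' @return Accumulated valley dose, Gy.
#' @export
#' @examples
#' accumulated_valley_dose_gy(0.14, irradiation_time_s(20, 2.3)) # ~1.2 Gy
accumulated_valley_dose_gy <- function(valley_rate_gy_min, time_s) {
  valley_rate_gy_min * time_s / 60
}

#' Stage positioning offsets for a plan
#'
#' Rigid 2D offset plus rotation mapping the planned beam centre onto the
#' home point marked by the positioning lasers.  Offsets are checked against
#' the motorised stage travel (50 mm in each translation axis, full
#' rotation).
#'
#' @param plan An [mrt_plan()].
#' @param home_point_mm Home-point position (x, y, z), mm.
#' @return A tibble with `dx_mm`, `dy_mm`, `rotation_deg`.
#' @export
positioning_offsets <- function(plan, home_point_mm = c(0, 0, 0)) {
  dx <- plan$isocenter_mm[1] + plan$beam_offset_mm[1] - home_point_mm[1]
  dy <- plan$isocenter_mm[2] + plan$beam_offset_mm[2] - home_point_mm[2]
  rot <- unname(plan$angles_deg["couch"] %||% 0)
  if (is.na(rot)) rot <- 0
  travel <- 50
  if (abs(dx) > travel || abs(dy) > travel) {
    abort(sprintf(
      "offset (%.1f, %.1f) mm exceeds the %g mm stage travel", dx, dy, travel))
  }
  tibble(dx_mm = dx, dy_mm = dy, rotation_deg = rot %% 360)
}

# resample a phantom onto the beam frame for couch/gantry rotations
# (nearest-neighbour lookup; identity when all angles are 0)
resample_phantom <- function(phantom, angles_deg) {
  if (all(abs(angles_deg) < 1e-9)) return(phantom)
  dims <- dim(phantom$density)
  vox <- phantom$voxel_mm
  ctr <- dims * vox / 2
  th_c <- angles_deg[["couch"]] * pi / 180    # rotation about the beam axis
  th_g <- angles_deg[["gantry"]] * pi / 180   # rotation about lateral y
  Rz <- matrix(c(cos(th_c), -sin(th_c), 0, sin(th_c), cos(th_c), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(th_g), 0, sin(th_g), 0, 1, 0, -sin(th_g), 0, cos(th_g)),
               3, 3, byrow = TRUE)
  R <- Rz %*% Ry
  grid <- as.matrix(expand.grid(x = (seq_len(dims[1]) - 0.5) * vox,
                                y = (seq_len(dims[2]) - 0.5) * vox,
                                z = (seq_len(dims[3]) - 0.5) * vox))
  src <- sweep(sweep(grid, 2, ctr) %*% t(R), 2, ctr, `+`)
  idx <- sweep(src, 2, rep(vox, 3), `/`)
  idx <- pmin(pmax(ceiling(idx), 1), matrix(dims, nrow(idx), 3, byrow = TRUE))
  lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
  out <- phantom
  out$material <- array(phantom$material[lin], dims)
  out$density <- array(phantom$density[lin], dims)
  out$roi <- lapply(phantom$roi, function(r) array(r[lin], dims))
  out
}

#' Compute a treatment plan report
#'
#' Runs the Monte Carlo photon stage over the phantom, reconstructs the
#' micrometre microbeam profile for the target ROI, and aggregates: mean
#' peak and valley dose rates, mean PVDR (both as the mean of per-voxel
#' ratios and as the ratio of means), mean FWHM and center-to-center
#' distance, the irradiation time for the prescription, the valley dose
#' accumulated over it, and the stage positioning offsets.
#'
#' @param phantom A [voxel_phantom()] whose ROI the plan targets.
#' @param plan An [mrt_plan()].
#' @param spectrum An [generate_spectrum()] result.
#' @param kernel Optional [electron_kernel()]; derived from the spectrum and
#'   the ROI's mean density when `NULL`.
#' @param n_histories Monte Carlo histories.
#' @param seed Seed for the Monte Carlo stage.
#' @param valley_mode Valley estimator, see [profile_metrics()].
#' @return An object of class `plan_report`.  Supports [glance()] (one-row
#'   tibble of the scalar plan quantities) and `print()`.
#' @export
compute_plan <- function(phantom, plan, spectrum, kernel = NULL,
                         n_histories = 2e5, seed = 1,
                         valley_mode = "midpoint") {
  geometry <- plan$geometry
  phantom <- resample_phantom(phantom, plan$angles_deg)
  roi <- if (is.character(plan$roi)) phantom$roi[[plan$roi]] else plan$roi
  if (is.null(roi) || !any(roi)) abort("plan ROI is empty or missing")
  dims <- dim(phantom$density)
  vox <- phantom$voxel_mm

  # ROI must sit inside the diverging beam
  ridx <- which(roi, arr.ind = TRUE)
  xc <- (ridx[, 1] - 0.5) * vox - dims[1] * vox / 2 - plan$beam_offset_mm[1]
  yc <- (ridx[, 2] - 0.5) * vox - dims[2] * vox / 2 - plan$beam_offset_mm[2]
  zc <- geometry$sd_mm + plan$gap_mm + (ridx[, 3] - 0.5) * vox
  mag <- zc / geometry$sd_mm
  outside <- abs(xc) > geometry$field_mm[1] / 2 * mag |
    abs(yc) > geometry$field_mm[2] / 2 * mag
  if (any(outside)) {
    abort(sprintf(
      "ROI extends outside the beam: lateral extent %.1f x %.1f mm vs field %g x %g mm",
      2 * max(abs(xc)), 2 * max(abs(yc)),
      geometry$field_mm[1], geometry$field_mm[2]))
  }

  dg <- simulate_photon_dose(phantom, geometry, spectrum, n_histories,
                             seed = seed, gap_mm = plan$gap_mm)
  if (is.null(kernel)) {
    kernel <- electron_kernel(spectrum,
                              density = mean(phantom$density[roi]))
  }

  # per-depth normalised pattern statistics (peak/valley of theta (*) K and
  # profile widths), shared by all ROI voxels in the slab
  rate <- plan$output_hist_per_min_mm2 *
    geometry$field_mm[1] * geometry$field_mm[2]
  slabs <- sort(unique(ridx[, 3]))
  stats_z <- purrr::map(slabs, function(iz) {
    dp <- mean(dg$d_primary[roi & slab_mask(dims, iz)])
    ds <- mean(dg$d_scatter[roi & slab_mask(dims, iz)])
    y <- geometry$sd_mm + plan$gap_mm + (iz - 0.5) * vox
    base <- reconstruct_profile(1, 0, geometry, kernel, y_mm = y)
    m0 <- profile_metrics(base, valley_mode)
    vl0_alt <- profile_metrics(
      base, setdiff(c("midpoint", "central50"), valley_mode))$valley_dose
    pr <- reconstruct_profile(dp * rate, ds * rate, geometry, kernel, y_mm = y)
    m <- profile_metrics(pr, valley_mode)
    list(iz = iz, pk0 = m0$peak_dose, vl0 = m0$valley_dose,
         vl0_alt = vl0_alt, ds_slab = ds,
         fwhm_um = m$fwhm_um, ctc_um = m$ctc_um)
  })
  names(stats_z) <- as.character(slabs)

  # per-voxel peak and valley dose rates; the scatter pedestal uses the
  # slab-average scatter dose (scatter is uniform within a voxel by model
  # assumption and varies slowly laterally, while per-voxel Monte Carlo
  # scatter estimates are noise-dominated at practical history counts)
  dp_v <- dg$d_primary[roi] * rate
  zkey <- as.character(ridx[, 3])
  pk0 <- vapply(zkey, function(z) stats_z[[z]]$pk0, numeric(1))
  vl0 <- vapply(zkey, function(z) stats_z[[z]]$vl0, numeric(1))
  vl0a <- vapply(zkey, function(z) stats_z[[z]]$vl0_alt, numeric(1))
  ds_v <- vapply(zkey, function(z) stats_z[[z]]$ds_slab, numeric(1)) * rate
  peak_v <- dp_v * pk0 + ds_v
  valley_v <- dp_v * vl0 + ds_v
  valley_v_alt <- dp_v * vl0a + ds_v

  mean_peak <- mean(peak_v)
  mean_valley <- mean(valley_v)
  t_s <- irradiation_time_s(plan$prescription_peak_gy, mean_peak)
  depth_tbl <- tibble(
    depth_mm = (slabs - 0.5) * vox,
    fwhm_um = vapply(stats_z, function(s) s$fwhm_um, numeric(1)),
    ctc_um = vapply(stats_z, function(s) s$ctc_um, numeric(1)))

  structure(list(
    mean_peak_dose_rate = mean_peak,
    mean_valley_dose_rate = mean_valley,
    mean_valley_dose_rate_alt = mean(valley_v_alt),
    mean_pvdr = mean_peak / mean_valley,
    mean_pvdr_voxelwise = mean(peak_v / valley_v),
    mean_fwhm_um = mean(depth_tbl$fwhm_um),
    mean_ctc_um = mean(depth_tbl$ctc_um),
    irradiation_time_s = t_s,
    accumulated_valley_dose_gy = accumulated_valley_dose_gy(mean_valley, t_s),
    prescription_peak_gy = plan$prescription_peak_gy,
    positioning = positioning_offsets(plan),
    depth_table = depth_tbl,
    n_roi_voxels = nrow(ridx),
    n_histories = n_histories, seed = as.integer(seed),
    valley_mode = valley_mode,
    dose_grid = dg, plan = plan),
    class = "plan_report")
}

slab_mask <- function(dims, iz) {
  m <- array(FALSE, dims)
  m[, , iz] <- TRUE
  m
}

#' @export
print.plan_report <- function(x, ...) {
  cat("<plan_report>\n")
  cat(sprintf("  mean peak dose rate   : %.3g Gy/min\n", x$mean_peak_dose_rate))
  cat(sprintf("  mean valley dose rate : %.3g Gy/min\n", x$mean_valley_dose_rate))
  cat(sprintf("  mean PVDR             : %.3g (ratio of means), %.3g (mean of ratios)\n",
              x$mean_pvdr, x$mean_pvdr_voxelwise))
  cat(sprintf("  mean FWHM / ctc       : %.0f / %.0f um\n",
              x$mean_fwhm_um, x$mean_ctc_um))
  cat(sprintf("  prescription          : %g Gy peak\n", x$prescription_peak_gy))
  cat(sprintf("  irradiation time      : %.0f s\n", round(x$irradiation_time_s)))
  cat(sprintf("  accumulated valley    : %.2g Gy\n", x$accumulated_valley_dose_gy))
  invisible(x)
}

#' Depth-resolved microbeam dose report
#'
#' For each depth slab of a dose grid, averages the primary and scatter
#' dose over a central lateral region, reconstructs the microbeam profile
#' at that depth, and extracts peak, valley, PVDR, FWHM and
#' center-to-center distance.  The valley-vs-depth curve is smoothed with a
#' short running mean and its interior local maxima are annotated (the
#' shallow maximum reflects scatter build-up; the deep one arises from
#' penumbral overlap of adjacent microbeams as the diverging beamlets
#' widen).
#'
#' @param dose_grid A [simulate_photon_dose()] result.
#' @param geometry The [beam_geometry()] used for the simulation.
#' @param kernel Optional [electron_kernel()].
#' @param lateral_halfwidth_mm Half-width of the central averaging region,
#'   mm.
#' @param valley_mode Valley estimator, see [profile_metrics()].
#' @param smooth_mm Running-mean window for the annotated valley curve, mm.
#' @return A tibble of class `depth_dose_table` with one row per depth:
#'   `depth_mm`, `d_primary`, `d_scatter`, `peak`, `valley`, `pvdr`,
#'   `fwhm_um`, `ctc_um`, `valley_smooth`; the attribute `valley_maxima`
#'   holds the depths and values of the interior local maxima of the
#'   smoothed valley curve.
#' @export
depth_dose_report <- function(dose_grid, geometry, kernel = NULL,
                              lateral_halfwidth_mm = 5,
                              valley_mode = "midpoint", smooth_mm = 5) {
  dims <- dim(dose_grid$d_primary)
  vox <- dose_grid$voxel_mm
  xc <- (seq_len(dims[1]) - 0.5) * vox - dims[1] * vox / 2
  yc <- (seq_len(dims[2]) - 0.5) * vox - dims[2] * vox / 2
  cx <- abs(xc) <= lateral_halfwidth_mm
  cy <- abs(yc) <= lateral_halfwidth_mm
  rows <- purrr::map_dfr(seq_len(dims[3]), function(iz) {
    dp <- mean(dose_grid$d_primary[cx, cy, iz])
    ds <- mean(dose_grid$d_scatter[cx, cy, iz])
    y <- geometry$sd_mm + dose_grid$gap_mm + (iz - 0.5) * vox
    pr <- reconstruct_profile(dp, ds, geometry, kernel, y_mm = y)
    m <- profile_metrics(pr, valley_mode)
    tibble(depth_mm = (iz - 0.5) * vox, d_primary = dp, d_scatter = ds,
           peak = m$peak_dose, valley = m$valley_dose, pvdr = m$pvdr,
           fwhm_um = m$fwhm_um, ctc_um = m$ctc_um)
  })
  width <- max(1L, round(smooth_mm / vox))
  rows$valley_smooth <- running_mean(rows$valley, width)
  maxima <- prominent_maxima(rows$depth_mm, rows$valley_smooth,
                             min_prominence = 0.02,
                             edge = max(2L, width %/% 2L + 1L))
  structure(rows, class = c("depth_dose_table", class(rows)),
            valley_maxima = maxima)
}

# interior local maxima of a curve, filtered by relative prominence: a
# maximum counts only if the curve dips below (1 - min_prominence) times
# the lower of it and its nearest accepted higher neighbour in between
prominent_maxima <- function(x, v, min_prominence = 0.02, edge = 2L) {
  n <- length(v)
  idx <- which(vapply(seq.int(edge + 1L, n - edge), function(i) {
    v[i] >= max(v[(i - 1):(i + 1)]) && v[i] > v[i - edge] && v[i] > v[i + edge]
  }, logical(1))) + edge
  if (!length(idx)) return(tibble(depth_mm = numeric(), valley = numeric()))
  ord <- idx[order(v[idx], decreasing = TRUE)]
  accepted <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      lo <- min(i, j); hi <- max(i, j)
      dip <- min(v[lo:hi])
      if (dip > (1 - min_prominence) * min(v[i], v[j])) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  tibble(depth_mm = x[accepted], valley = v[accepted])
}

#' @export
glance.plan_report <- function(x, ...) {
  tibble(mean_peak_dose_rate = x$mean_peak_dose_rate,
         mean_valley_dose_rate = x$mean_valley_dose_rate,
         mean_pvdr = x$mean_pvdr,
         mean_pvdr_voxelwise = x$mean_pvdr_voxelwise,
         mean_fwhm_um = x$mean_fwhm_um,
         mean_ctc_um = x$mean_ctc_um,
         prescription_peak_gy = x$prescription_peak_gy,
         irradiation_time_s = x$irradiation_time_s,
         accumulated_valley_dose_gy = x$accumulated_valley_dose_gy,
         n_roi_voxels = x$n_roi_voxels,
         n_histories = x$n_histories)
}
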