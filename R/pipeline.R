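# Configuration-driven pipeline: read a YAML run configuration, execute
# simulate -> reconstruct -> plan -> report, write a manifest next to the
# outputs.  All randomness flows from the single config seed.

#' Read a run configuration
#'
#' The YAML schema has blocks `geometry` (sd_mm, slit_um, ctc_um, field_mm,
#' sigma_mm, tilt_deg), `spectrum` (kvp, filtration_mm_al, or `file` with a
#' two-column CSV), `phantom` (either `file`, a NIfTI HU volume, or a
#' synthetic `recipe`: `slab` with dims_mm/material, or `mouse_head`),
#' `plan` (prescription_peak_gy, roi, gap_mm, beam_offset_mm,
#' isocenter_mm), and `execution` (seed, histories, voxel_mm).
#'
#' @param path Path to a YAML configuration.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config", path = path)
}

config_geometry <- function(cfg) {
  g <- cfg$geometry %||% list()
  beam_geometry(
    sd_mm = g$sd_mm %||% 212,
    field_mm = unlist(g$field_mm %||% c(20, 20)),
    tilt_deg = g$tilt_deg %||% 8,
    focal_spot = focal_spot(g$sigma_mm %||% 0.58),
    collimator = collimator(slit_um = g$slit_um %||% 30,
                            ctc_um = g$ctc_um %||% 400))
}

config_spectrum <- function(cfg) {
  s <- cfg$spectrum %||% list()
  if (!is.null(s$file)) {
    tab <- read.csv(s$file, comment.char = "#")
    return(generate_spectrum(s$kvp %||% max(tab$energy_kev),
                             s$filtration_mm_al %||% 0, table = tab))
  }
  generate_spectrum(s$kvp %||% 225, s$filtration_mm_al %||% 1)
}

config_phantom <- function(cfg) {
  p <- cfg$phantom %||% list()
  vox <- cfg$execution$voxel_mm %||% 1
  if (!is.null(p$file)) {
    if (!file.exists(p$file)) {
      abort(sprintf("phantom file not found: %s", p$file))
    }
    return(read_phantom_nifti(p$file))
  }
  recipe <- p$recipe %||% "slab"
  if (identical(recipe, "mouse_head")) {
    make_mouse_head_phantom(voxel_mm = vox)
  } else {
    make_slab_phantom(unlist(p$dims_mm %||% c(20, 40, 20)),
                      p$material %||% "pmma", voxel_mm = vox)
  }
}

#' Tag the in-beam core of a phantom as an ROI
#'
#' Adds a `"beam"` ROI covering the voxels whose centres lie inside a
#' central fraction of the diverging field at their depth; used to give
#' homogeneous slab phantoms a target region.
#'
#' @param phantom A [voxel_phantom()].
#' @param geometry A [beam_geometry()].
#' @param gap_mm Collimator-to-phantom distance, mm.
#' @param margin Fraction of the projected field half-width retained.
#' @return The phantom with an added `roi$beam` mask.
#' @export
tag_beam_roi <- function(phantom, geometry, gap_mm = 4, margin = 0.8) {
  dims <- dim(phantom$density)
  vox <- phantom$voxel_mm
  xc <- (seq_len(dims[1]) - 0.5) * vox - dims[1] * vox / 2
  yc <- (seq_len(dims[2]) - 0.5) * vox - dims[2] * vox / 2
  zc <- geometry$sd_mm + gap_mm + (seq_len(dims[3]) - 0.5) * vox
  mask <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    hx <- geometry$field_mm[1] / 2 * zc[k] / geometry$sd_mm * margin
    hy <- geometry$field_mm[2] / 2 * zc[k] / geometry$sd_mm * margin
    mask[, , k] <- outer(abs(xc) <= hx, abs(yc) <= hy, `&`)
  }
  phantom$roi$beam <- mask
  phantom
}

#' Run the full planning pipeline from a configuration
#'
#' Executes the photon Monte Carlo stage, the profile reconstruction, the
#' plan aggregation and the depth report, and writes `plan_report.json`,
#' `depth_dose.csv` and `manifest.json` into `out_dir`.  Outputs carry no
#' timestamps, so identical configurations and seeds give byte-identical
#' reports.  On failure an `INCOMPLETE` marker file is left in `out_dir`.
#'
#' @param config A path to a YAML configuration or a [read_run_config()]
#'   result.
#' @param out_dir Output directory (created if needed).
#' @return The `plan_report`, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  on.exit(if (file.exists(marker)) NULL, add = TRUE)

  geometry <- config_geometry(config)
  spectrum <- config_spectrum(config)
  phantom <- config_phantom(config)
  ex <- config$execution %||% list()
  seed <- ex$seed %||% 1
  histories <- ex$histories %||% 1e5
  pl <- config$plan %||% list()
  gap <- pl$gap_mm %||% 4
  if (!length(phantom$roi)) {
    phantom <- tag_beam_roi(phantom, geometry, gap_mm = gap)
  }
  roi_name <- pl$roi %||% names(phantom$roi)[1]
  if (!roi_name %in% names(phantom$roi)) {
    phantom <- tag_beam_roi(phantom, geometry, gap_mm = gap)
    if (identical(roi_name, "beam")) NULL else
      abort(sprintf("phantom has no ROI named '%s'", roi_name))
  }
  plan <- mrt_plan(geometry,
                   prescription_peak_gy = pl$prescription_peak_gy %||% 20,
                   roi = roi_name,
                   isocenter_mm = unlist(pl$isocenter_mm %||% c(0, 0, 0)),
                   beam_offset_mm = unlist(pl$beam_offset_mm %||% c(0, 0)),
                   gap_mm = gap)

  report <- compute_plan(phantom, plan, spectrum,
                         n_histories = histories, seed = seed)
  depth <- depth_dose_report(report$dose_grid, geometry)

  rep_json <- glance(report)
  rep_json$seed <- seed
  jsonlite::write_json(as.list(rep_json), file.path(out_dir, "plan_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(as_tibble(depth), file.path(out_dir, "depth_dose.csv"),
            row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mrtplan")),
    seed = seed, histories = histories,
    config_md5 = if (!is.null(attr(config, "path")))
      unname(tools::md5sum(attr(config, "path"))) else NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  file.remove(marker)
  invisible(report)
}

#' Export a fluence pattern or profile as CSV
#'
#' Two-column CSV writers for the tabular result types.
#'
#' @param x A `fluence_pattern`, `microbeam_profile` or `kernel1d` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
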