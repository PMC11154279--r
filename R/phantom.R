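#' Voxel phantom container
#'
#' A `voxel_phantom` is a 3D grid of material labels and mass densities.
#' Array axes are ordered (x, y, z) with z the beam (depth) axis; voxel
#' indexing is 0-based and half-open in physical coordinates, the first
#' z-slab being the beam entrance.
#'
#' @param material Character 3D array (or vector reshaped by `dim`) of
#'   material names from [list_materials()].
#' @param density Numeric 3D array of mass densities, g/cm^3.
#' @param voxel_mm Isotropic voxel edge length, mm.
#' @param roi Optional named list of logical arrays (same dim) tagging
#'   regions of interest.
#' @return An object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(material, density, voxel_mm = 1, roi = list()) {
  if (!identical(dim(material), dim(density))) {
    abort("`material` and `density` must have identical dimensions")
  }
  if (length(dim(density)) != 3L) abort("phantom arrays must be 3D")
  if (any(density < 0)) abort("densities must be non-negative")
  bad <- setdiff(unique(as.vector(material)), list_materials()$name)
  if (length(bad)) abort(sprintf("unknown material(s): %s",
                                 paste(bad, collapse = ", ")))
  structure(list(material = material, density = density,
                 voxel_mm = voxel_mm, roi = roi),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels @ %g mm (%g x %g x %g mm^3)\n",
              d[1], d[2], d[3], x$voxel_mm,
              d[1] * x$voxel_mm, d[2] * x$voxel_mm, d[3] * x$voxel_mm))
  cat("  materials:", paste(sort(unique(as.vector(x$material))), collapse = ", "), "\n")
  if (length(x$roi)) cat("  ROI tags:", paste(names(x$roi), collapse = ", "), "\n")
  invisible(x)
}

#' Homogeneous slab phantom
#'
#' Builds a homogeneous rectangular phantom, e.g. the thick PMMA calibration
#' phantom (100 x 54 x 54 mm^3) or the validation phantom (20 x 40 x 20
#' mm^3).  Dimensions are given as (lateral x, lateral y, depth z) in mm;
#' dimensions that are not multiples of the voxel size are rounded up with a
#' warning.
#'
#' @param dims_mm Length-3 physical dimensions (x, y, z) in mm; `z` is depth
#'   along the beam.
#' @param material Material name.
#' @param voxel_mm Voxel size in mm.
#' @param density Override density, g/cm^3 (defaults to the material's
#'   nominal density).
#' @return A [voxel_phantom()].
#' @export
#' @examples
#' ph <- make_slab_phantom(c(54, 54, 100), "pmma")
make_slab_phantom <- function(dims_mm, material = "pmma", voxel_mm = 1,
                              density = NULL) {
  if (length(dims_mm) != 3L || any(dims_mm <= 0)) {
    abort("`dims_mm` must be 3 positive lengths (x, y, z)")
  }
  n <- dims_mm / voxel_mm
  if (any(abs(n - round(n)) > 1e-9)) {
    warn("dimensions are not multiples of the voxel size; rounding up")
  }
  n <- as.integer(ceiling(n - 1e-9))
  density <- density %||% material_meta(material)$meta$density_g_cm3
  voxel_phantom(array(material, dim = n), array(density, dim = n), voxel_mm)
}

#' Layered mouse-head phantom
#'
#' Synthetic stack along the beam axis emulating the treatment situation of
#' a mouse head on a PMMA bed: bed, skin/soft tissue, skull bone, brain
#' (soft tissue), skull bone, skin.  Layer thicknesses are chosen so that
#' with the defaults the brain occupies depths 9-15 mm from the phantom
#' entrance; the brain layer is tagged as the `"brain"` ROI.
#'
#' @param brain_thickness_mm Brain thickness along the beam, mm.
#' @param bed_mm PMMA bed thickness, mm.
#' @param pre_soft_mm Soft tissue between bed and skull, mm.
#' @param skull_mm Skull bone thickness (each side), mm; 0 gives a pure
#'   soft-tissue stack on the bed.
#' @param post_soft_mm Soft tissue beyond the far skull, mm.
#' @param lateral_mm Lateral extent (x and y), mm.
#' @param voxel_mm Voxel size, mm.
#' @return A [voxel_phantom()] with a `"brain"` ROI.
#' @export
#' @examples
#' ph <- make_mouse_head_phantom()
#' range(which(apply(ph$roi$brain, 3, any))) # brain slabs (1-based)
make_mouse_head_phantom <- function(brain_thickness_mm = 6, bed_mm = 3,
                                    pre_soft_mm = 5, skull_mm = 1,
                                    post_soft_mm = 2, lateral_mm = 20,
                                    voxel_mm = 1) {
  layers <- tibble(
    material = c("pmma", "soft_tissue", "bone_cortical", "soft_tissue",
                 "bone_cortical", "soft_tissue"),
    thickness = c(bed_mm, pre_soft_mm, skull_mm, brain_thickness_mm,
                  skull_mm, post_soft_mm),
    is_brain = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  layers <- layers[layers$thickness > 0, ]
  nz_per <- as.integer(round(layers$thickness / voxel_mm))
  nz <- sum(nz_per)
  nx <- as.integer(round(lateral_mm / voxel_mm))
  mat_z <- rep(layers$material, nz_per)
  brain_z <- rep(layers$is_brain, nz_per)
  dens <- vapply(mat_z, function(m) material_meta(m)$meta$density_g_cm3,
                 numeric(1))
  material <- array(rep(mat_z, each = nx * nx), dim = c(nx, nx, nz))
  density <- array(rep(dens, each = nx * nx), dim = c(nx, nx, nz))
  roi <- array(rep(brain_z, each = nx * nx), dim = c(nx, nx, nz))
  voxel_phantom(material, density, voxel_mm, roi = list(brain = roi))
}

#' Convert a phantom to Hounsfield units and back
#'
#' `phantom_to_hu()` inverts the CT conversion of [hu_to_material()] for the
#' four CT material classes (air, lung, soft tissue, bone); materials outside
#' the CT image (e.g. PMMA, tungsten) are mapped through the density ramp and
#' will reclassify on the way back.  `phantom_from_hu()` builds a phantom
#' from an HU array via [hu_to_material()].
#'
#' @param phantom A [voxel_phantom()].
#' @return `phantom_to_hu()`: a numeric HU array; `phantom_from_hu()`: a
#'   [voxel_phantom()].
#' @export
phantom_to_hu <- function(phantom) {
  hu <- material_to_hu(as.vector(phantom$material),
                       as.vector(phantom$density))
  array(hu, dim = dim(phantom$density))
}

#' @rdname phantom_to_hu
#' @param hu Numeric 3D array of Hounsfield units.
#' @param voxel_mm Voxel size in mm.
#' @export
phantom_from_hu <- function(hu, voxel_mm = 1) {
  conv <- hu_to_material(as.vector(hu))
  voxel_phantom(array(conv$material, dim = dim(hu)),
                array(conv$density_g_cm3, dim = dim(hu)),
                voxel_mm)
}

#' Read and write phantoms as NIfTI volumes
#'
#' Phantoms are stored as an HU volume in NIfTI format (any reader can load
#' it) plus a JSON sidecar naming the voxel size and ROI tags.
#'
#' @param phantom A [voxel_phantom()].
#' @param path Output path for the `.nii.gz` volume; the sidecar gets the
#'   same stem with `.json`.
#' @return `write_phantom_nifti()` returns `path` invisibly;
#'   `read_phantom_nifti()` returns a [voxel_phantom()].
#' @export
write_phantom_nifti <- function(phantom, path) {
  img <- RNifti::asNifti(phantom_to_hu(phantom),
                         pixdim = rep(phantom$voxel_mm, 3))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(voxel_mm = phantom$voxel_mm,
                            roi = names(phantom$roi)),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phantom_nifti
#' @export
read_phantom_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_mm <- RNifti::pixdim(img)[1]
  phantom_from_hu(array(as.numeric(img), dim = dim(img)), voxel_mm = voxel_mm)
}
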