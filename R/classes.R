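#' Projection stack
#'
#' An angle-indexed set of 2D OPT projection frames. Frames are stored as a
#' numeric array with dim `(nz, width, n_angles)`: rows run along the
#' rotation (vertical) axis, columns along the detector, and the third index
#' over rotation angles.
#'
#' @param data numeric array `(nz, width, n_angles)`.
#' @param angles_deg numeric vector of frame angles in degrees, one per frame.
#' @param pixel_size_um physical detector pixel size (microns); projections
#'   are assumed isotropic.
#' @param cor_offset_px signed horizontal offset of the rotation axis from the
#'   detector center, in pixels, if known (e.g. from simulation or after
#'   alignment). `NA` when unknown.
#' @param meta free-form metadata list (provenance, preprocessing flags).
#' @return An object of class `projection_stack`.
#' @export
projection_stack <- function(data, angles_deg, pixel_size_um,
                             cor_offset_px = NA_real_, meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("projection data must be a 3D array (nz, width, n_angles)")
  if (dim(data)[3L] != length(angles_deg))
    stop("number of frames (", dim(data)[3L], ") does not match number of angles (",
         length(angles_deg), ")")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(list(data = data, angles_deg = as.double(angles_deg),
                 pixel_size_um = as.double(pixel_size_um),
                 cor_offset_px = as.double(cor_offset_px), meta = meta),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<projection_stack> %d frames of %d x %d px, %.3g um/px\n",
              d[3L], d[1L], d[2L], x$pixel_size_um))
  cat(sprintf("  angles: %.1f..%.1f deg; cor_offset_px: %s\n",
              min(x$angles_deg), max(x$angles_deg),
              ifelse(is.na(x$cor_offset_px), "unknown", format(x$cor_offset_px))))
  invisible(x)
}

#' @export
dim.projection_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3L]

#' Isotropic 3D intensity volume
#'
#' Reconstructed (or simulated) voxel grid. Data are stored with dim
#' `(ny, nx, nz)`; `vol$data[, , k]` is the k-th axial (z) section. The voxel
#' size is a single number: the parallel-beam model used throughout the
#' package assumes isotropic voxels.
#'
#' @param data numeric 3D array `(ny, nx, nz)`.
#' @param voxel_size_um isotropic voxel edge length in microns.
#' @param meta free-form metadata list.
#' @return An object of class `opt_volume`.
#' @export
opt_volume <- function(data, voxel_size_um, meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array (ny, nx, nz)")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L || voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number; anisotropic voxels are not supported")
  structure(list(data = data, voxel_size_um = as.double(voxel_size_um), meta = meta),
            class = "opt_volume")
}

#' @export
print.opt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<opt_volume> %d x %d x %d voxels @ %.3g um, range [%.3g, %.3g]\n",
              d[1L], d[2L], d[3L], x$voxel_size_um, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.opt_volume <- function(x) dim(x$data)

#' Labeled component volume
#'
#' Integer voxel grid where 0 is background and positive labels are
#' consecutive connected components, plus the parameters that produced it.
#'
#' @param labels integer 3D array.
#' @param voxel_size_um isotropic voxel size (microns).
#' @param provenance list recording the segmentation parameters and input
#'   hash that produced the labels.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size_um, provenance = list()) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels < 0L)) stop("labels must be non-negative")
  structure(list(labels = labels, voxel_size_um = as.double(voxel_size_um),
                 provenance = provenance),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d components\n",
              paste(dim(x$labels), collapse = " x "), max(x$labels)))
  invisible(x)
}

n_labels <- function(lv) max(lv$labels)
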