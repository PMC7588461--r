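# TIFF + YAML-sidecar I/O. Stacks and volumes travel as multi-page grayscale
# TIFF with a sidecar next to them (same path, .yaml extension) recording the
# geometry and the linear value scaling applied for integer storage.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yaml")

# Scale data into [0,1] for TIFF storage. Integer-valued non-negative data
# fitting 16 bits are stored losslessly against a fixed 65535 scale; other
# data are min/max normalized (float32 storage is lossy at ~1e-7 relative).
storage_scaling <- function(data, bits) {
  if (bits == 16L && all(data >= 0) && all(data <= 65535) &&
      all(data == round(data))) {
    list(min = 0, scale = 65535, dtype = "uint16")
  } else {
    lo <- min(data)
    hi <- max(data)
    list(min = lo, scale = max(hi - lo, .Machine$double.eps),
         dtype = if (bits == 16L) "uint16_scaled" else "float32")
  }
}

write_pages <- function(data, path, bits, scaling) {
  pages <- lapply(seq_len(dim(data)[3L]), function(i)
    pmin(pmax((data[, , i] - scaling$min) / scaling$scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
}

read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bad <- which(vapply(pages, function(p) length(dim(p)) > 2L, logical(1)))
  if (length(bad))
    stop("page ", bad[1L], " of ", path, " is not single-channel grayscale ",
         "(RGB/multi-sample TIFF variants are not supported)")
  array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
}

restore_scaling <- function(raw, sc) {
  out <- raw * sc$scale + sc$min
  if (identical(sc$dtype, "uint16")) out <- round(out)
  out
}

#' Write a projection stack as multi-page TIFF plus a YAML sidecar
#'
#' One page per rotation angle. Integer-valued stacks within 16 bits are
#' stored losslessly; other data are linearly rescaled with the scale
#' recorded in the sidecar (`value_min`, `value_scale`, `dtype`). The
#' sidecar also carries `angles_deg`, `pixel_size_um` and `cor_offset_px`.
#'
#' @param stack a [projection_stack()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @param bits 16 (integer) or 32 (float32) bits per sample.
#' @return Invisibly, `path`.
#' @export
write_projection_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "projection_stack"), bits %in% c(16L, 32L))
  sc <- storage_scaling(stack$data, bits)
  write_pages(stack$data, path, bits, sc)
  side <- list(angles_deg = as.double(stack$angles_deg),
               pixel_size_um = stack$pixel_size_um,
               cor_offset_px = stack$cor_offset_px,
               value_min = sc$min, value_scale = sc$scale, dtype = sc$dtype)
  yaml::write_yaml(side, sidecar_path(path), precision = 15L)
  invisible(path)
}

#' Read a projection stack written by [write_projection_stack()]
#'
#' @param path TIFF path (sidecar expected next to it).
#' @return A [projection_stack()]. Errors if the sidecar is missing (naming
#'   the required keys) or if the page count does not match the sidecar's
#'   angle list; non-uniform angle spacing is recorded with a warning.
#' @export
read_projection_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar ", sp, ": a YAML file with keys angles_deg and ",
         "pixel_size_um (plus optional cor_offset_px) is required")
  side <- yaml::read_yaml(sp)
  for (key in c("angles_deg", "pixel_size_um"))
    if (is.null(side[[key]]))
      stop("sidecar ", sp, " lacks required key '", key, "'")
  raw <- read_pages(path)
  ang <- as.double(unlist(side$angles_deg))
  if (dim(raw)[3L] != length(ang))
    stop("stack has ", dim(raw)[3L], " pages but sidecar lists ",
         length(ang), " angles")
  sc <- list(min = side$value_min %||% 0, scale = side$value_scale %||% 1,
             dtype = side$dtype %||% "float32")
  data <- restore_scaling(raw, sc)
  meta <- list()
  if (length(ang) > 2L) {
    steps <- diff(ang)
    if (diff(range(steps)) > 1e-6 * max(abs(steps))) {
      warning("sidecar angles are not uniformly spaced; recording for downstream tolerance")
      meta$nonuniform_angles <- TRUE
    }
  }
  projection_stack(data, ang, side$pixel_size_um,
                   cor_offset_px = side$cor_offset_px %||% NA_real_, meta = meta)
}

#' Write a volume as multi-page TIFF (one page per z section) plus sidecar
#' @param volume an [opt_volume()].
#' @param path output TIFF path.
#' @param bits 16 or 32 bits per sample (float volumes default to float32).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, bits = 32L) {
  stopifnot(inherits(volume, "opt_volume"), bits %in% c(16L, 32L))
  sc <- storage_scaling(volume$data, bits)
  write_pages(volume$data, path, bits, sc)
  yaml::write_yaml(list(voxel_size_um = volume$voxel_size_um,
                        value_min = sc$min, value_scale = sc$scale,
                        dtype = sc$dtype),
                   sidecar_path(path), precision = 15L)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#' @param path TIFF path.
#' @return An [opt_volume()].
#' @export
read_volume <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar ", sp, ": a YAML file with key voxel_size_um is required")
  side <- yaml::read_yaml(sp)
  if (is.null(side$voxel_size_um))
    stop("sidecar ", sp, " lacks required key 'voxel_size_um'")
  raw <- read_pages(path)
  sc <- list(min = side$value_min %||% 0, scale = side$value_scale %||% 1,
             dtype = side$dtype %||% "float32")
  opt_volume(restore_scaling(raw, sc), side$voxel_size_um)
}

# Labeled volumes as lossless 16-bit TIFF (labels are small integers).
write_label_volume <- function(labels, path) {
  lab <- if (inherits(labels, "label_volume")) labels$labels else labels
  if (max(lab) > 65535L) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  vs <- if (inherits(labels, "label_volume")) labels$voxel_size_um else NA_real_
  sc <- list(min = 0, scale = 65535, dtype = "uint16")
  write_pages(lab, path, 16L, sc)
  yaml::write_yaml(list(voxel_size_um = vs, value_min = 0, value_scale = 65535,
                        dtype = "uint16", kind = "labels"),
                   sidecar_path(path), precision = 15L)
  invisible(path)
}

read_label_volume <- function(path) {
  side <- yaml::read_yaml(sidecar_path(path))
  raw <- read_pages(path)
  lab <- round(raw * 65535)
  storage.mode(lab) <- "integer"
  label_volume(lab, side$voxel_size_um %||% NA_real_)
}
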