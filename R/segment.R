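#' Segmentation parameters
#'
#' Knobs of the 3D segmentation stages: baseline estimation, thresholding,
#' connected components, the voxel number filter and rule-based artifact
#' removal. Every value is recorded in the provenance of the label volumes
#' it produces.
#'
#' @param baseline_method `"gaussian_background"` (subtract a heavily
#'   smoothed copy of the volume; default) or `"percentile_constant"`
#'   (subtract a constant in-mask percentile).
#' @param baseline_sigma_um Gaussian sigma of the background estimate,
#'   microns; must be much larger than an islet (default 200 um).
#' @param baseline_percentile percentile for `"percentile_constant"`.
#' @param threshold_method `"otsu"` (default) or `"k_sigma"`; both are
#'   invariant to global linear intensity rescaling. Otsu lands near half the
#'   object amplitude -- the full-width-at-half-maximum convention that sizes
#'   blurred spheres without bias -- whereas a low k-sigma detection
#'   threshold includes the reconstruction point-spread skirt and inflates
#'   diameters.
#' @param k multiplier on the robust background spread for `"k_sigma"`.
#' @param min_voxels voxel number filter: components smaller than this are
#'   dropped. Default 27 (a 3x3x3 minimum resolvable islet).
#' @param connectivity 6, 18 or 26 (default 26, so islets are not split
#'   across diagonal voxel contacts).
#' @param elongation_max artifact filter: components whose longest/shortest
#'   bounding-box extent ratio exceeds this are removed (hairs are thin and
#'   long; default 6).
#' @param border_exclude drop components touching the volume border.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(baseline_method = c("gaussian_background",
                                                    "percentile_constant"),
                                baseline_sigma_um = 200,
                                baseline_percentile = 50,
                                threshold_method = c("otsu", "k_sigma"),
                                k = 4, min_voxels = 27L,
                                connectivity = 26L, elongation_max = 6,
                                border_exclude = TRUE) {
  stopifnot(min_voxels >= 1L, k > 0, elongation_max > 0,
            connectivity %in% c(6L, 18L, 26L), baseline_sigma_um > 0,
            baseline_percentile >= 0, baseline_percentile <= 100)
  structure(list(baseline_method = match.arg(baseline_method),
                 baseline_sigma_um = baseline_sigma_um,
                 baseline_percentile = baseline_percentile,
                 threshold_method = match.arg(threshold_method),
                 k = k, min_voxels = as.integer(min_voxels),
                 connectivity = as.integer(connectivity),
                 elongation_max = elongation_max,
                 border_exclude = isTRUE(border_exclude)),
            class = "segmentation_params")
}

#' Segment the tissue (specimen) mask of a reconstructed volume
#'
#' Global Otsu threshold, largest connected component, morphological closing
#' with a 2-voxel ball, then 3D hole filling (dark interior regions such as
#' low-autofluorescence tumor tissue belong to the specimen, not the
#' background). Otsu on continuous data is invariant to global linear
#' intensity rescaling, so the mask does not depend on the reconstruction's
#' absolute gray values.
#'
#' @param volume an [opt_volume()].
#' @return A logical 3D array covering the specimen.
#' @export
tissue_mask <- function(volume) {
  stopifnot(inherits(volume, "opt_volume"))
  v <- volume$data
  thr <- otsu_threshold(as.vector(v))
  m <- v > thr
  if (!any(m)) stop("no tissue detected: volume has no voxels above the Otsu threshold")
  lab <- cpp_label3d(as.logical(m), as.integer(dim(v)), 26L)
  counts <- tabulate(lab[lab > 0L])
  m <- array(lab == which.max(counts), dim = dim(v))
  fill_holes3(close3(m, 2))
}

#' Subtract the diffuse background (baseline) of a volume
#'
#' `gaussian_background`: subtracts a heavily smoothed copy of the in-mask
#' intensity (normalized convolution, so tissue edges do not bleed into the
#' estimate) and clips at zero. `percentile_constant`: subtracts the stated
#' in-mask percentile. Voxels outside the tissue mask are zeroed.
#'
#' @param volume an [opt_volume()].
#' @param params a [segmentation_params()].
#' @param mask tissue mask from [tissue_mask()] (computed if missing).
#' @return An [opt_volume()] of non-negative baseline-subtracted intensity.
#' @export
subtract_baseline <- function(volume, params = segmentation_params(),
                              mask = NULL) {
  stopifnot(inherits(volume, "opt_volume"))
  if (is.null(mask)) mask <- tissue_mask(volume)
  v <- volume$data
  if (params$baseline_method == "gaussian_background") {
    sigma_vox <- params$baseline_sigma_um / volume$voxel_size_um
    if (sigma_vox < 2)
      stop(sprintf("baseline sigma of %.3g um is under 2 voxels at %.3g um/voxel; increase baseline_sigma_um",
                   params$baseline_sigma_um, volume$voxel_size_um))
    # normalized convolution inside the mask, then a second pass with the
    # bright foreground excluded so dense islet signal does not inflate the
    # background estimate
    baseline <- masked_background(v, mask * 1.0, sigma_vox)
    resid1 <- (v - baseline)[mask]
    med1 <- median(resid1)
    sig1 <- med1 - quantile(resid1, pnorm(-1), names = FALSE)
    if (sig1 > 0) {
      w <- mask & (v - baseline <= med1 + 2 * sig1)
      baseline <- masked_background(v, w * 1.0, sigma_vox)
    }
  } else {
    baseline <- quantile(v[mask], params$baseline_percentile / 100, names = FALSE)
  }
  resid <- (v - baseline)[mask]
  # robust background spread from the lower (foreground-free) half of the
  # residual distribution: bright objects only populate the upper tail
  med <- median(resid)
  sigma_bg <- med - quantile(resid, pnorm(-1), names = FALSE)
  out <- pmax(v - baseline, 0) * mask
  opt_volume(out, volume$voxel_size_um,
             meta = c(volume$meta,
                      list(baseline_method = params$baseline_method,
                           background_median = med, background_sigma = sigma_bg)))
}

# Threshold above background for the k_sigma method. Prefers the background
# statistics recorded by subtract_baseline (clipping at zero makes the plain
# MAD of the subtracted volume degenerate); otherwise falls back to robust
# statistics of the values themselves.
k_sigma_threshold <- function(values, k, meta = NULL) {
  if (!is.null(meta$background_sigma) && meta$background_sigma > 0)
    return(max(meta$background_median, 0) + k * meta$background_sigma)
  med <- median(values)
  spread <- mad(values)
  if (spread == 0) spread <- quantile(values, pnorm(1), names = FALSE) - med
  if (is.na(spread) || spread <= 0) spread <- sd(values)
  if (is.na(spread) || spread <= 0) spread <- .Machine$double.eps
  med + k * spread
}

masked_background <- function(v, w, sigma_vox) {
  num <- gaussian_blur3(v * w, sigma_vox)
  den <- gaussian_blur3(w, sigma_vox)
  num / pmax(den, 1e-9)
}

segmentation_threshold <- function(values, params, meta = NULL) {
  if (params$threshold_method == "otsu") return(otsu_threshold(values))
  k_sigma_threshold(values, params$k, meta)
}

#' Label bright islet-like objects in a baseline-subtracted volume
#'
#' Thresholds the in-mask intensity with a scale-invariant method, labels
#' connected components under the declared connectivity, applies the voxel
#' number filter and relabels consecutively.
#'
#' @param volume baseline-subtracted [opt_volume()] (see
#'   [subtract_baseline()]).
#' @param params a [segmentation_params()].
#' @param mask tissue mask (computed from `volume` if missing).
#' @return A [label_volume()].
#' @export
label_islets <- function(volume, params = segmentation_params(), mask = NULL) {
  stopifnot(inherits(volume, "opt_volume"))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(volume$data))
  v <- volume$data
  thr <- segmentation_threshold(v[mask], params, volume$meta)
  m <- (v > thr) & mask
  lab <- cpp_label3d(as.logical(m), as.integer(dim(v)), params$connectivity)
  lab <- filter_min_voxels(lab, params$min_voxels)
  label_volume(lab, volume$voxel_size_um,
               provenance = list(params = unclass(params), threshold = thr,
                                 input_hash = md5_of(volume$data)))
}

# Drop components below the voxel count floor and relabel consecutively,
# preserving raster order of first occurrence.
filter_min_voxels <- function(lab, min_voxels) {
  nl <- max(lab)
  if (nl == 0L) return(lab)
  counts <- tabulate(lab[lab > 0L], nbins = nl)
  keep <- which(counts >= min_voxels)
  remap <- integer(nl)
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim = dim(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  out
}

#' Remove hair- and artifact-like components from a label volume
#'
#' Drops components whose bounding-box elongation (longest over shortest
#' axis extent) exceeds `elongation_max` -- tiny hairs and streak artifacts
#' are thin and long, islets are compact -- and, when `border_exclude` is
#' set, components touching the volume border. Survivors are relabeled
#' consecutively.
#'
#' @param labels a [label_volume()].
#' @param params a [segmentation_params()].
#' @return The filtered [label_volume()].
#' @export
remove_artifacts <- function(labels, params = segmentation_params()) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  nl <- max(lab)
  if (nl == 0L) return(labels)
  st <- cpp_label_stats(lab, as.integer(dim(lab)), numeric(0))
  ey <- st$ymax - st$ymin + 1L
  ex <- st$xmax - st$xmin + 1L
  ez <- st$zmax - st$zmin + 1L
  elong <- pmax(ey, ex, ez) / pmin(ey, ex, ez)
  keep <- elong <= params$elongation_max
  if (params$border_exclude) {
    d <- dim(lab)
    keep <- keep & st$ymin > 0L & st$xmin > 0L & st$zmin > 0L &
      st$ymax < d[1L] - 1L & st$xmax < d[2L] - 1L & st$zmax < d[3L] - 1L
  }
  remap <- integer(nl)
  remap[which(keep)] <- seq_len(sum(keep))
  out <- array(0L, dim = dim(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  label_volume(out, labels$voxel_size_um,
               provenance = c(labels$provenance,
                              list(artifact_filter = list(
                                elongation_max = params$elongation_max,
                                border_exclude = params$border_exclude))))
}

#' Delineate the low-autofluorescence (tumor-like) region
#'
#' Within the tissue mask, splits intensities at the in-mask Otsu threshold
#' and keeps the connected low-intensity components of at least `min_voxels`
#' voxels. In pancreatic autofluorescence data, tumor (PDAC) tissue is
#' markedly darker than normal parenchyma, so this low-intensity region is
#' the 3D tumor-delineation surrogate. An empty low region (a tumor-free
#' specimen) returns an empty mask with a warning, not an error.
#'
#' @param volume a reconstructed [opt_volume()] (not baseline subtracted).
#' @param params a [segmentation_params()].
#' @param mask tissue mask (computed if missing).
#' @param border_margin_vox erosion (voxels) applied to the tissue mask
#'   before the split: the partial-volume shell at the specimen surface is
#'   dark for optical, not histological, reasons and would otherwise join
#'   the low-intensity class.
#' @return A logical 3D mask of the low-intensity region.
#' @export
delineate_low_af_region <- function(volume, params = segmentation_params(),
                                    mask = NULL, border_margin_vox = 2) {
  stopifnot(inherits(volume, "opt_volume"))
  if (is.null(mask)) mask <- tissue_mask(volume)
  if (border_margin_vox > 0) mask <- erode3(mask, border_margin_vox)
  v <- volume$data
  thr <- otsu_threshold(v[mask])
  low <- (v < thr) & mask
  lab <- cpp_label3d(as.logical(low), as.integer(dim(v)), params$connectivity)
  lab <- filter_min_voxels(lab, params$min_voxels)
  out <- array(lab > 0L, dim = dim(v))
  if (!any(out))
    warning("no low-autofluorescence region found: returning an empty mask (tumor-free volume?)")
  out
}
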