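#' Measure per-islet statistics
#'
#' One record per labeled component: voxel count, physical volume, the
#' axis-aligned bounding-box extents, the mean 3D diameter -- the arithmetic
#' mean of the x, y and z extents, the categorization norm used for islet
#' size distributions -- centroid, and the intensity sum over the component's
#' voxels.
#'
#' @param labels a [label_volume()].
#' @param intensity the matching [opt_volume()] (same grid and voxel size).
#' @return A data.frame with columns `label_id`, `voxel_count`, `volume_um3`,
#'   `extent_y_um`, `extent_x_um`, `extent_z_um`, `mean_diameter_um`,
#'   `centroid_y`, `centroid_x`, `centroid_z` (1-based voxel coordinates) and
#'   `intensity_sum`.
#' @export
measure_islets <- function(labels, intensity) {
  stopifnot(inherits(labels, "label_volume"), inherits(intensity, "opt_volume"))
  if (!all(dim(labels$labels) == dim(intensity$data)))
    stop("label and intensity volumes have different grids: ",
         paste(dim(labels$labels), collapse = "x"), " vs ",
         paste(dim(intensity$data), collapse = "x"))
  if (abs(labels$voxel_size_um - intensity$voxel_size_um) > 1e-9)
    stop("label and intensity volumes have different voxel sizes")
  vs <- labels$voxel_size_um
  nl <- max(labels$labels)
  if (nl == 0L)
    return(data.frame(label_id = integer(), voxel_count = integer(),
                      volume_um3 = double(), extent_y_um = double(),
                      extent_x_um = double(), extent_z_um = double(),
                      mean_diameter_um = double(), centroid_y = double(),
                      centroid_x = double(), centroid_z = double(),
                      intensity_sum = double()))
  st <- cpp_label_stats(labels$labels, as.integer(dim(labels$labels)),
                        as.double(intensity$data))
  ey <- (st$ymax - st$ymin + 1L) * vs
  ex <- (st$xmax - st$xmin + 1L) * vs
  ez <- (st$zmax - st$zmin + 1L) * vs
  data.frame(label_id = seq_len(nl), voxel_count = as.integer(st$count),
             volume_um3 = st$count * vs^3,
             extent_y_um = ey, extent_x_um = ex, extent_z_um = ez,
             mean_diameter_um = (ex + ey + ez) / 3,
             centroid_y = st$cy + 1, centroid_x = st$cx + 1,
             centroid_z = st$cz + 1,
             intensity_sum = st$sum)
}

#' Per-object intensity statistics
#'
#' Sum, mean and max of the intensity over each labeled component (the
#' statistic used for intensity-coded object displays).
#'
#' @inheritParams measure_islets
#' @return A data.frame with `label_id`, `intensity_sum`, `intensity_mean`,
#'   `intensity_max`.
#' @export
per_object_intensity_stats <- function(labels, intensity) {
  rec <- measure_islets(labels, intensity)
  if (nrow(rec) == 0L)
    return(data.frame(label_id = integer(), intensity_sum = double(),
                      intensity_mean = double(), intensity_max = double()))
  st <- cpp_label_stats(labels$labels, as.integer(dim(labels$labels)),
                        as.double(intensity$data))
  data.frame(label_id = rec$label_id, intensity_sum = st$sum,
             intensity_mean = st$sum / st$count, intensity_max = st$max)
}

#' Maximum intensity projection
#'
#' Element-wise maximum of the volume along one axis.
#'
#' @param volume an [opt_volume()] (or plain 3D array).
#' @param axis `"y"`, `"x"` or `"z"`.
#' @return A 2D matrix.
#' @export
mip <- function(volume, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  v <- if (inherits(volume, "opt_volume")) volume$data else as.array(volume)
  margin <- switch(axis, y = c(2L, 3L), x = c(1L, 3L), z = c(1L, 2L))
  apply(v, margin, max)
}

#' Bin islet records into a size distribution
#'
#' Categorizes islets by mean 3D diameter into half-open bins `[lo, hi)` --
#' a value on an interior edge falls in the upper bin -- and reports counts,
#' count fractions, and the per-category summed islet volume with its
#' fractions (the mass-weighted variant of the distribution).
#'
#' @param records data.frame from [measure_islets()] (needs
#'   `mean_diameter_um` and `volume_um3`).
#' @param edges_um strictly increasing bin edges covering every record.
#' @return A `size_distribution`: `category_edges_um`, `counts`, `fractions`,
#'   `volume_um3`, `volume_fractions`, `n_total`.
#' @export
size_distribution <- function(records, edges_um = seq(0, 400, by = 25)) {
  stopifnot(is.data.frame(records), length(edges_um) >= 2L)
  if (any(diff(edges_um) <= 0)) stop("category edges must be strictly increasing")
  d <- records$mean_diameter_um
  if (length(d) == 0L) stop("no islet records to bin")
  outside <- d < edges_um[1L] | d >= edges_um[length(edges_um)]
  if (any(outside))
    stop("islet diameters outside the category range [",
         edges_um[1L], ", ", edges_um[length(edges_um)], "): ",
         paste(format(sort(d[outside])), collapse = ", "))
  ncat <- length(edges_um) - 1L
  bin <- findInterval(d, edges_um)
  counts <- tabulate(bin, nbins = ncat)
  volsum <- vapply(seq_len(ncat),
                   function(b) sum(records$volume_um3[bin == b]), numeric(1))
  structure(list(category_edges_um = as.double(edges_um),
                 counts = as.integer(counts),
                 fractions = counts / length(d),
                 volume_um3 = volsum,
                 volume_fractions = if (sum(volsum) > 0) volsum / sum(volsum)
                                    else volsum,
                 n_total = length(d)),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %d islets in %d categories (%g..%g um)\n",
              x$n_total, length(x$counts), min(x$category_edges_um),
              max(x$category_edges_um)))
  invisible(x)
}

#' Build a size distribution from a reference fraction table
#'
#' Reference stereology tables (e.g. published whole-pancreas islet size
#' distributions) are supplied as a CSV with columns `category_lo_um`,
#' `category_hi_um`, `fraction`; bins must be contiguous.
#'
#' @param path CSV file path.
#' @return A `size_distribution` with fractions but `NA` counts.
#' @export
read_reference_distribution <- function(path) {
  tab <- read.csv(path)
  need <- c("category_lo_um", "category_hi_um", "fraction")
  if (!all(need %in% names(tab)))
    stop("reference CSV must have columns: ", paste(need, collapse = ", "))
  if (any(abs(tab$category_lo_um[-1L] - head(tab$category_hi_um, -1L)) > 1e-9))
    stop("reference categories must be contiguous")
  structure(list(category_edges_um = c(tab$category_lo_um, tab$category_hi_um[nrow(tab)]),
                 counts = rep(NA_integer_, nrow(tab)),
                 fractions = tab$fraction / sum(tab$fraction),
                 volume_um3 = rep(NA_real_, nrow(tab)),
                 volume_fractions = rep(NA_real_, nrow(tab)),
                 n_total = NA_integer_),
            class = "size_distribution")
}

#' Compare a measured size distribution against a reference
#'
#' Reports per-category fraction differences, the total-variation distance,
#' and the chi-square statistic of the observed counts against the reference
#' fractions (dof = n_categories - 1). Numbers only; no verdict is attached.
#'
#' @param dist measured [size_distribution()] (with counts).
#' @param reference reference `size_distribution` on identical edges.
#' @return A list: `per_category` data.frame, `tv_distance`, `chisq`, `dof`.
#' @export
compare_to_reference <- function(dist, reference) {
  stopifnot(inherits(dist, "size_distribution"),
            inherits(reference, "size_distribution"))
  if (length(dist$category_edges_um) != length(reference$category_edges_um) ||
      any(abs(dist$category_edges_um - reference$category_edges_um) > 1e-9))
    stop("size distributions use different category edges; rebin before comparing")
  diff_frac <- dist$fractions - reference$fractions
  expected <- reference$fractions * dist$n_total
  nz <- expected > 0
  chisq <- sum((dist$counts[nz] - expected[nz])^2 / expected[nz])
  list(per_category = data.frame(
         category_lo_um = head(dist$category_edges_um, -1L),
         category_hi_um = dist$category_edges_um[-1L],
         fraction = dist$fractions, reference_fraction = reference$fractions,
         fraction_diff = diff_frac),
       tv_distance = 0.5 * sum(abs(diff_frac)),
       chisq = chisq, dof = length(dist$counts) - 1L)
}

fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Export islet statistics to CSV files
#'
#' Writes `islets.csv` (one record per row), `distribution.csv`
#' (per-category counts, fractions and summed volumes) and, when a
#' comparison report is given, `comparison.csv`. Doubles are written at full
#' precision (`%.17g`) so a read-back reproduces the records exactly, and
#' output is bit-stable given identical inputs.
#'
#' @param records data.frame from [measure_islets()].
#' @param dist a [size_distribution()] (optional).
#' @param report a [compare_to_reference()] report (optional).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_statistics <- function(records, dist = NULL, report = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "islets.csv")
  write_csv_full(records, p)
  paths <- c(paths, p)
  if (!is.null(dist)) {
    dd <- data.frame(category_lo_um = head(dist$category_edges_um, -1L),
                     category_hi_um = dist$category_edges_um[-1L],
                     count = dist$counts, fraction = dist$fractions,
                     volume_um3 = dist$volume_um3,
                     volume_fraction = dist$volume_fractions)
    p <- file.path(dir, "distribution.csv")
    write_csv_full(dd, p)
    paths <- c(paths, p)
  }
  if (!is.null(report)) {
    cc <- report$per_category
    cc$tv_distance <- report$tv_distance
    cc$chisq <- report$chisq
    cc$dof <- report$dof
    p <- file.path(dir, "comparison.csv")
    write_csv_full(cc, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
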