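#' Phantom specification
#'
#' Parameters of a synthetic autofluorescence pancreas phantom: a bright
#' ellipsoidal parenchyma block containing droplet-like bright islets with a
#' lognormal diameter law, optional straight vessel-like tubes, and an
#' optional darker embedded ellipsoid standing in for low-autofluorescence
#' tumor tissue.
#'
#' @param shape_vox integer vector `(ny, nx, nz)`: voxel grid size; in-plane
#'   slices must be square (`ny == nx`) for the parallel-beam projector.
#' @param voxel_size_um isotropic voxel size in microns.
#' @param n_islets number of spherical islets to place (non-overlapping,
#'   rejection sampled).
#' @param islet_diameter_log_mu,islet_diameter_log_sigma mean and sd of
#'   `log(diameter/um)`: islet diameters are drawn from
#'   `Lognormal(log_mu, log_sigma)`. Defaults `log(100)` and `0.4` give the
#'   right-skewed ~50-300 um range typical of human islets.
#' @param islet_intensity,parenchyma_intensity voxel intensities of islet and
#'   parenchyma tissue (arbitrary autofluorescence units). The islet to
#'   parenchyma ratio is a free contrast parameter, not a tissue claim.
#' @param tumor optional list `(center_vox, semi_axes_vox, intensity_factor)`
#'   describing a darker ellipsoid; `intensity_factor` must be in `[0, 1)` so
#'   the tumor is strictly darker than parenchyma.
#' @param n_vessels number of straight cylindrical vessel-like tubes.
#' @param vessel_radius_um,vessel_intensity vessel geometry and intensity.
#' @param min_separation_vox minimum clearance (voxels) between islet
#'   surfaces. Tangent spheres are connected after voxelization and objects
#'   closer than the reconstruction point-spread width are unresolvable by
#'   any segmentation, so a phantom meant for recovery validation must keep
#'   distinct islets separated by at least the system resolution; the
#'   default of 3 voxels is the approximate width of the filtered
#'   back-projection point spread.
#' @param baseline_amplitude amplitude (as a fraction of
#'   `parenchyma_intensity`) of a smooth linear illumination gradient added
#'   inside the tissue; 0 disables it.
#' @param seed integer seed; the same spec is bit-identical across calls.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape_vox = c(96L, 96L, 96L), voxel_size_um = 10,
                         n_islets = 25L,
                         islet_diameter_log_mu = log(100),
                         islet_diameter_log_sigma = 0.4,
                         islet_intensity = 3, parenchyma_intensity = 1,
                         min_separation_vox = 3,
                         tumor = NULL,
                         n_vessels = 0L, vessel_radius_um = 30,
                         vessel_intensity = 2,
                         baseline_amplitude = 0, seed = 1L) {
  stopifnot(length(shape_vox) == 3L, all(shape_vox >= 8L),
            voxel_size_um > 0, n_islets >= 0L,
            islet_diameter_log_sigma >= 0, islet_intensity > 0,
            min_separation_vox >= 0,
            parenchyma_intensity > 0, n_vessels >= 0L,
            vessel_radius_um > 0, vessel_intensity > 0,
            baseline_amplitude >= 0)
  if (shape_vox[1L] != shape_vox[2L])
    stop("in-plane slices must be square (ny == nx)")
  if (!is.null(tumor)) {
    stopifnot(is.list(tumor),
              length(tumor$center_vox) == 3L, length(tumor$semi_axes_vox) == 3L)
    if (is.null(tumor$intensity_factor) ||
        tumor$intensity_factor < 0 || tumor$intensity_factor >= 1)
      stop("tumor intensity_factor must lie in [0, 1): the tumor is strictly darker than parenchyma")
  }
  structure(list(shape_vox = as.integer(shape_vox), voxel_size_um = voxel_size_um,
                 n_islets = as.integer(n_islets),
                 islet_diameter_log_mu = islet_diameter_log_mu,
                 islet_diameter_log_sigma = islet_diameter_log_sigma,
                 islet_intensity = islet_intensity,
                 min_separation_vox = min_separation_vox,
                 parenchyma_intensity = parenchyma_intensity,
                 tumor = tumor, n_vessels = as.integer(n_vessels),
                 vessel_radius_um = vessel_radius_um,
                 vessel_intensity = vessel_intensity,
                 baseline_amplitude = baseline_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoidal tissue support: semi-axes at 90% of the inscribed half-extents
# in-plane, so all projections stay inside the detector, and 95% axially.
tissue_support <- function(shape) {
  ny <- shape[1L]; nx <- shape[2L]; nz <- shape[3L]
  ctr <- (shape + 1) / 2
  semi <- c(0.45 * ny, 0.45 * nx, 0.475 * nz)
  y <- (seq_len(ny) - ctr[1L]) / semi[1L]
  x <- (seq_len(nx) - ctr[2L]) / semi[2L]
  z <- (seq_len(nz) - ctr[3L]) / semi[3L]
  r2 <- outer(outer(y^2, x^2, `+`), z^2, `+`)
  list(mask = r2 <= 1, center = ctr, semi = semi)
}

# Fraction of the unit ellipsoid radius at which a point of margin m (voxels)
# still fits entirely inside: used to keep whole islets within tissue.
inside_ellipsoid <- function(p, center, semi, margin) {
  sum(((p - center) / (semi - margin))^2) <= 1
}

paint_sphere <- function(arr, center, radius_vox, value) {
  d <- dim(arr)
  lo <- pmax(1L, floor(center - radius_vox))
  hi <- pmin(d, ceiling(center + radius_vox))
  ys <- lo[1L]:hi[1L]; xs <- lo[2L]:hi[2L]; zs <- lo[3L]:hi[3L]
  r2 <- outer(outer((ys - center[1L])^2, (xs - center[2L])^2, `+`),
              (zs - center[3L])^2, `+`)
  sub <- arr[ys, xs, zs]
  sub[r2 <= radius_vox^2] <- value
  arr[ys, xs, zs] <- sub
  arr
}

#' Generate a ground-truthed phantom volume
#'
#' Builds the intensity volume described by a [phantom_spec()] together with
#' its voxel-exact ground truth: a label volume (0 background, 1 parenchyma,
#' 2 tumor, 3 vessel, labels >= 4 one per islet) and a per-islet table of
#' true centers, diameters and analytic volumes.
#'
#' Islets are non-overlapping spheres placed by rejection sampling fully
#' inside the tissue support; placement failing after `10 * n_islets`
#' attempts raises an error naming the crowding parameters.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (an [opt_volume()]), `label_volume`
#'   (integer array), `islet_table` (data.frame: id, cy, cx, cz, diameter_um,
#'   volume_um3), and `tissue_mask` (logical array).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  shape <- spec$shape_vox
  vs <- spec$voxel_size_um
  sup <- tissue_support(shape)
  vol <- array(0, dim = shape)
  vol[sup$mask] <- spec$parenchyma_intensity
  lab <- array(0L, dim = shape)
  lab[sup$mask] <- 1L

  if (spec$baseline_amplitude > 0) {
    # smooth linear illumination gradient in a random direction, scaled 0..1
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    g <- outer(outer(seq_len(shape[1L]) * dir[1L], seq_len(shape[2L]) * dir[2L], `+`),
               seq_len(shape[3L]) * dir[3L], `+`)
    g <- (g - min(g)) / max(1e-12, diff(range(g)))
    vol <- vol + spec$baseline_amplitude * spec$parenchyma_intensity * g * sup$mask
  }

  if (!is.null(spec$tumor)) {
    tc <- spec$tumor$center_vox
    ta <- spec$tumor$semi_axes_vox
    y <- (seq_len(shape[1L]) - tc[1L]) / ta[1L]
    x <- (seq_len(shape[2L]) - tc[2L]) / ta[2L]
    z <- (seq_len(shape[3L]) - tc[3L]) / ta[3L]
    inside <- outer(outer(y^2, x^2, `+`), z^2, `+`) <= 1
    inside <- inside & sup$mask
    vol[inside] <- spec$parenchyma_intensity * spec$tumor$intensity_factor
    lab[inside] <- 2L
  }

  if (spec$n_vessels > 0L) {
    rad_vox <- spec$vessel_radius_um / vs
    g <- expand.grid(y = seq_len(shape[1L]), x = seq_len(shape[2L]),
                     z = seq_len(shape[3L]))
    pts <- cbind(g$y, g$x, g$z)
    for (i in seq_len(spec$n_vessels)) {
      p0 <- sup$center + (runif(3) - 0.5) * sup$semi
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      rel <- sweep(pts, 2L, p0)
      proj <- as.vector(rel %*% u)
      d2 <- rowSums(rel^2) - proj^2
      hit <- d2 <= rad_vox^2 & as.vector(sup$mask)
      vol[hit] <- spec$vessel_intensity
      lab[hit] <- 3L
    }
  }

  n <- spec$n_islets
  islet_table <- data.frame(id = integer(), cy = double(), cx = double(),
                            cz = double(), diameter_um = double(),
                            volume_um3 = double())
  if (n > 0L) {
    diam_um <- rlnorm(n, spec$islet_diameter_log_mu, spec$islet_diameter_log_sigma)
    centers <- matrix(0, n, 3L)
    rad_vox <- diam_um / vs / 2
    # place the largest spheres first (easier packing; placement order does
    # not alter the drawn diameter law)
    ord <- order(rad_vox, decreasing = TRUE)
    placed_idx <- integer(0)
    attempts <- 0L
    max_attempts <- 100L * n
    lo <- sup$center - sup$semi
    span <- 2 * sup$semi
    for (i in ord) {
      r <- rad_vox[i]
      repeat {
        # draw a candidate fully inside the tissue support; geometric
        # rejections are free, only overlap rejections consume the budget
        for (try in seq_len(1000L)) {
          cand <- lo + runif(3) * span
          if (inside_ellipsoid(cand, sup$center, sup$semi, r + 1)) break
          if (try == 1000L)
            stop(sprintf("islet of diameter %.3g um does not fit the %s-voxel tissue support",
                         diam_um[i], paste(shape, collapse = "x")))
        }
        ok <- TRUE
        if (length(placed_idx)) {
          prev <- centers[placed_idx, , drop = FALSE]
          dist2 <- rowSums(sweep(prev, 2L, cand)^2)
          ok <- all(dist2 > (rad_vox[placed_idx] + r + spec$min_separation_vox)^2)
        }
        if (ok) break
        attempts <- attempts + 1L
        if (attempts >= max_attempts)
          stop(sprintf(paste0("could not place %d non-overlapping islets in a %s-voxel ",
                              "tissue support after %d overlap rejections (placed %d); reduce ",
                              "n_islets or the diameter law (log_mu=%.3g, log_sigma=%.3g)"),
                       n, paste(shape, collapse = "x"), max_attempts,
                       length(placed_idx), spec$islet_diameter_log_mu,
                       spec$islet_diameter_log_sigma))
      }
      centers[i, ] <- cand
      placed_idx <- c(placed_idx, i)
    }
    for (i in seq_len(n)) {
      vol <- paint_sphere(vol, centers[i, ], rad_vox[i], spec$islet_intensity)
      lab <- paint_sphere(lab, centers[i, ], rad_vox[i], i + 3L)
    }
    islet_table <- data.frame(id = seq_len(n), cy = centers[, 1L],
                              cx = centers[, 2L], cz = centers[, 3L],
                              diameter_um = diam_um,
                              volume_um3 = pi / 6 * diam_um^3)
  }
  storage.mode(lab) <- "integer"
  list(volume = opt_volume(vol, vs, meta = list(phantom_seed = spec$seed)),
       label_volume = lab, islet_table = islet_table, tissue_mask = sup$mask)
}

#' Acquisition specification for the simulated OPT scan
#'
#' @param n_angles number of uniformly spaced projection angles (>= 2).
#' @param angular_range_deg total rotation covered; 360 for a full turn (the
#'   normal OPT protocol). Angles are `range * (0:(n-1)) / n`.
#' @param cor_offset_px signed horizontal offset of the rotation axis from
#'   the detector center, applied identically to every frame.
#' @param noise_model one of `"none"`, `"gaussian"`, `"poisson_gaussian"`.
#' @param noise_scale Gaussian sigma as a fraction of the stack's parenchyma
#'   signal level (the median positive projection value); for
#'   `poisson_gaussian` the same reference level is mapped to 10^4 expected
#'   photons before Gaussian read noise is added.
#' @param seed integer seed for the noise draw.
#' @return An `acquisition_spec` list.
#' @export
acquisition_spec <- function(n_angles = 400L, angular_range_deg = 360,
                             cor_offset_px = 0, noise_model = "none",
                             noise_scale = 0, seed = 1L) {
  noise_model <- match.arg(noise_model, c("none", "gaussian", "poisson_gaussian"))
  stopifnot(n_angles >= 2L, angular_range_deg > 0, noise_scale >= 0)
  structure(list(n_angles = as.integer(n_angles),
                 angular_range_deg = angular_range_deg,
                 cor_offset_px = cor_offset_px, noise_model = noise_model,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Simulate OPT projection acquisition (parallel-beam forward projection)
#'
#' Computes the discrete line integral of the volume along the optical axis
#' after rotating it about the vertical (z) axis by each frame angle, then
#' shifts the projections horizontally by the center-of-rotation offset and
#' applies the configured noise model. This is the forward model whose exact
#' inverse (in the noiseless dense-angle limit) is filtered back-projection.
#'
#' @param volume an [opt_volume()] with square in-plane slices.
#' @param acq an [acquisition_spec()].
#' @return A [projection_stack()] with one frame per angle and the (known)
#'   simulated `cor_offset_px` recorded in its metadata.
#' @export
forward_project <- function(volume, acq) {
  stopifnot(inherits(volume, "opt_volume"), inherits(acq, "acquisition_spec"))
  d <- dim(volume$data)
  if (d[1L] != d[2L])
    stop("parallel-beam projection requires square in-plane slices (ny == nx)")
  angles_deg <- acq$angular_range_deg * (seq_len(acq$n_angles) - 1L) / acq$n_angles
  raw <- cpp_forward_project(as.double(volume$data), as.integer(d),
                             angles_deg * pi / 180, acq$cor_offset_px)
  raw <- add_acquisition_noise(raw, acq)
  projection_stack(raw, angles_deg, volume$voxel_size_um,
                   cor_offset_px = acq$cor_offset_px,
                   meta = list(noise_model = acq$noise_model,
                               noise_scale = acq$noise_scale,
                               acq_seed = acq$seed))
}

add_acquisition_noise <- function(raw, acq) {
  if (acq$noise_model == "none") return(raw)
  pos <- raw[raw > 0]
  ref <- if (length(pos)) median(pos) else 0
  d <- dim(raw)
  out <- with_seed(acq$seed, {
    x <- raw
    if (acq$noise_model == "poisson_gaussian" && ref > 0) {
      gain <- ref / 1e4  # reference signal level = 10^4 expected photons
      x <- rpois(length(x), pmax(x, 0) / gain) * gain
    }
    if (acq$noise_scale > 0 && ref > 0)
      x <- x + rnorm(length(x), 0, acq$noise_scale * ref)
    x
  })
  dim(out) <- d
  out
}
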