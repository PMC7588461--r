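#' Reconstruction parameters
#'
#' @param filter frequency window applied on top of the band-limited ramp:
#'   `"hann"` (default; strongest noise suppression), `"shepp_logan"`, or the
#'   plain `"ramp"`.
#' @param circle_mask zero voxels outside the inscribed in-plane circle,
#'   where parallel-beam data do not determine the image.
#' @return A `reconstruction_params` list.
#' @export
reconstruction_params <- function(filter = c("hann", "ramp", "shepp_logan"),
                                  circle_mask = TRUE) {
  structure(list(filter = match.arg(filter), circle_mask = isTRUE(circle_mask),
                 interpolation = "linear"),
            class = "reconstruction_params")
}

#' Rearrange a projection stack into per-row sinograms
#'
#' Sinogram `r` holds detector row `r` of every frame: an
#' `(n_angles, width)` matrix per reconstructed section. This is a lossless
#' transpose of the stack array.
#'
#' @param stack a [projection_stack()] with uniformly spaced angles.
#' @param tol relative tolerance on the uniformity of the angular spacing.
#' @return A `sinogram_set`: array `(n_angles, width, nz)` plus angles and
#'   pixel size.
#' @export
to_sinograms <- function(stack, tol = 1e-6) {
  stopifnot(inherits(stack, "projection_stack"))
  ang <- stack$angles_deg
  if (length(ang) > 1L) {
    steps <- diff(ang)
    if (diff(range(steps)) > tol * max(abs(steps)))
      stop("projection angles are not uniformly spaced; resample before reconstruction")
  }
  structure(list(data = aperm(stack$data, c(3L, 2L, 1L)), angles_deg = ang,
                 pixel_size_um = stack$pixel_size_um,
                 cor_offset_px = stack$cor_offset_px),
            class = "sinogram_set")
}

#' Reassemble a projection stack from sinograms (inverse of [to_sinograms()])
#' @param sinos a `sinogram_set`.
#' @return A [projection_stack()].
#' @export
from_sinograms <- function(sinos) {
  stopifnot(inherits(sinos, "sinogram_set"))
  projection_stack(aperm(sinos$data, c(3L, 2L, 1L)), sinos$angles_deg,
                   sinos$pixel_size_um, cor_offset_px = sinos$cor_offset_px)
}

# Frequency response of the reconstruction filter on a padded row of length
# n: the band-limited ramp of Kak & Slaney (spatial taps h(0) = 1/4,
# h(odd k) = -1/(pi k)^2), doubled so that the pi/(2 n_angles)
# back-projection scale recovers density, times the chosen window.
fbp_filter_response <- function(n, filter) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2 - 1):1))
  h <- numeric(n)
  h[1L] <- 0.25
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi * k[odd])^2
  H <- 2 * Re(fft(h))
  w <- abs(k) / (n / 2) # normalized frequency 0..1
  win <- switch(filter,
                ramp = rep(1, n),
                shepp_logan = {
                  s <- rep(1, n)
                  nz <- w > 0
                  s[nz] <- sin(pi * w[nz] / 2) / (pi * w[nz] / 2)
                  s
                },
                hann = 0.5 + 0.5 * cos(pi * w))
  H * win
}

next_pow2 <- function(n) 2^ceiling(log2(n))

filter_sinogram <- function(sino, filter) {
  na <- nrow(sino); W <- ncol(sino)
  P <- max(64L, next_pow2(2L * W))
  H <- fbp_filter_response(P, filter)
  padded <- matrix(0, P, na)
  padded[seq_len(W), ] <- t(sino)
  filt <- Re(mvfft(mvfft(padded) * H, inverse = TRUE)) / P
  t(filt[seq_len(W), , drop = FALSE])
}

#' Filtered back-projection of a single sinogram
#'
#' Standard parallel-beam FBP: each angular row is filtered in the frequency
#' domain with the windowed band-limited ramp (rows zero-padded to a power of
#' two), then back-projected with linear interpolation and scaled by
#' `pi / (2 n_angles)`. Angles are expected to span 180 degrees; use
#' [reconstruct_volume()] for 360-degree stacks (it folds conjugate rays
#' first).
#'
#' @param sino numeric matrix `(n_angles, width)`.
#' @param angles_deg projection angles of the rows, degrees.
#' @param params a [reconstruction_params()].
#' @return A `width x width` matrix (y, x): the reconstructed section.
#' @export
fbp <- function(sino, angles_deg, params = reconstruction_params()) {
  sino <- as.matrix(sino)
  if (nrow(sino) < 2L) stop("need at least 2 angles for reconstruction")
  if (nrow(sino) != length(angles_deg))
    stop("sinogram rows must match the number of angles")
  if (any(!is.finite(sino)))
    stop("sinogram contains NaN/Inf values; clean the projections before reconstruction")
  filt <- filter_sinogram(sino, params$filter)
  sec <- cpp_backproject(filt, angles_deg * pi / 180) * pi / (2 * nrow(sino))
  if (params$circle_mask) {
    W <- ncol(sino)
    ctr <- (W + 1) / 2
    r2 <- outer((seq_len(W) - ctr)^2, (seq_len(W) - ctr)^2, `+`)
    sec[r2 > (W / 2)^2] <- 0
  }
  sec
}

# Average conjugate rays of a full-turn sinogram set into a 180-degree set;
# requires an even number of uniformly spaced angles.
fold_full_turn <- function(sinos) {
  na <- length(sinos$angles_deg)
  na2 <- na %/% 2L
  W <- dim(sinos$data)[2L]
  first <- sinos$data[seq_len(na2), , , drop = FALSE]
  second <- sinos$data[na2 + seq_len(na2), W:1, , drop = FALSE]
  sinos$data <- (first + second) / 2
  sinos$angles_deg <- sinos$angles_deg[seq_len(na2)]
  sinos
}

#' Reconstruct a volume from an aligned projection stack
#'
#' Applies [to_sinograms()] and [fbp()] per detector row and assembles the
#' sections into an isotropic [opt_volume()]. Full-turn (360 degree) stacks
#' with an even angle count are first reduced by averaging conjugate rays
#' into a 180-degree sinogram, which halves the work and averages noise; an
#' odd full-turn angle count is back-projected directly with the scale
#' doubled.
#'
#' @param stack an aligned [projection_stack()].
#' @param params a [reconstruction_params()].
#' @return An [opt_volume()] with voxel size equal to the projection pixel
#'   size.
#' @export
reconstruct_volume <- function(stack, params = reconstruction_params()) {
  stopifnot(inherits(stack, "projection_stack"))
  if (!is.na(stack$cor_offset_px) && abs(stack$cor_offset_px) > 0.05)
    warning(sprintf("stack metadata reports cor_offset_px = %.2f; reconstruct from an aligned stack",
                    stack$cor_offset_px))
  sinos <- to_sinograms(stack)
  ang <- sinos$angles_deg
  na <- length(ang)
  span <- if (na > 1L) (ang[2L] - ang[1L]) * na else 0
  scale_mult <- 1
  if (abs(span - 360) < 1e-3) {
    if (na %% 2L == 0L) sinos <- fold_full_turn(sinos)
    else scale_mult <- 2 # each direction sampled twice over the full turn
  }
  nz <- dim(sinos$data)[3L]
  W <- dim(sinos$data)[2L]
  vol <- array(0, dim = c(W, W, nz))
  angles_rad <- sinos$angles_deg * pi / 180
  P <- max(64L, next_pow2(2L * W))
  H <- fbp_filter_response(P, params$filter)
  na_eff <- length(sinos$angles_deg)
  ctr <- (W + 1) / 2
  r2 <- outer((seq_len(W) - ctr)^2, (seq_len(W) - ctr)^2, `+`)
  outside <- r2 > (W / 2)^2
  for (r in seq_len(nz)) {
    sino <- sinos$data[, , r]
    if (any(!is.finite(sino)))
      stop("sinogram for section ", r, " contains NaN/Inf values")
    padded <- matrix(0, P, na_eff)
    padded[seq_len(W), ] <- t(sino)
    filt <- t(Re(mvfft(mvfft(padded) * H, inverse = TRUE))[seq_len(W), , drop = FALSE] / P)
    sec <- cpp_backproject(filt, angles_rad) * scale_mult * pi / (2 * na_eff)
    if (params$circle_mask) sec[outside] <- 0
    vol[, , r] <- sec
  }
  opt_volume(vol, stack$pixel_size_um,
             meta = list(filter = params$filter, n_angles = na,
                         folded = abs(span - 360) < 1e-3 && na %% 2L == 0L))
}
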