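# Misalignment detection and correction: the rotation axis of an OPT scan
# rarely sits exactly on the detector center column. The offset is estimated
# by discrete-Fourier-transform registration of conjugate (theta, theta+180)
# frame pairs: the 180-degree frame, mirrored horizontally, equals the
# 0-degree frame translated by twice the center-of-rotation offset.

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

fft_freqs <- function(n) c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))

# Evaluate the phase-correlation surface cc(delta) = IDFT[cross power](delta)
# on a continuous (delta1, delta2) grid by a small matrix-multiply DFT.
correlation_surface <- function(xp_n, d1, d2) {
  n1 <- nrow(xp_n); n2 <- ncol(xp_n)
  k1 <- exp(2i * pi / n1 * outer(d1, fft_freqs(n1)))
  k2 <- exp(2i * pi / n2 * outer(fft_freqs(n2), d2))
  (k1 %*% xp_n %*% k2) / (n1 * n2)
}

# Sub-pixel translation between two equally sized frames by phase
# correlation: coarse peak from the inverse FFT of the normalized cross-power
# spectrum, then refinement on an upsampled local grid (spacing 1/upsample).
# Returns the shift (drow, dcol) such that b is (approximately) a translated
# by that amount, plus the correlation peak height in [0, 1].
phase_correlate <- function(a, b, upsample = 10L) {
  stopifnot(all(dim(a) == dim(b)))
  d <- dim(a)
  w <- outer(hann_window(d[1L]), hann_window(d[2L]))
  fa <- fft(a * w)
  fb <- fft(b * w)
  xp <- fa * Conj(fb)
  xp_n <- xp / pmax(Mod(xp), .Machine$double.eps)
  cc <- fft(xp_n, inverse = TRUE) / length(xp_n)
  peak <- which.max(Mod(cc))
  pr <- (peak - 1L) %% d[1L]
  pc <- (peak - 1L) %/% d[1L]
  delta <- c(pr, pc)
  delta <- ifelse(delta > d / 2, delta - d, delta)
  quality <- min(1, Mod(cc[peak]))
  if (upsample > 1L) {
    # the coarse peak is within half a pixel of the optimum; scan +-0.75 px
    d1 <- delta[1L] + seq(-0.75, 0.75, by = 1 / upsample)
    d2 <- delta[2L] + seq(-0.75, 0.75, by = 1 / upsample)
    cu <- Mod(correlation_surface(xp_n, d1, d2))
    pk <- which.max(cu) - 1L
    delta <- c(d1[pk %% length(d1) + 1L], d2[pk %/% length(d1) + 1L])
  }
  # the correlation peak sits at minus the displacement of b relative to a
  list(shift = -delta, peak = quality)
}

#' Estimate the center-of-rotation offset of a projection stack
#'
#' For every conjugate frame pair (theta, theta + 180 within
#' `angular_tol_deg`), the second frame is mirrored horizontally and the
#' sub-pixel translation between the pair is found by DFT phase correlation
#' (Hann-windowed, upsampled cross-correlation). Half the recovered
#' horizontal shift is that pair's center-of-rotation estimate; the robust
#' aggregate is the median over pairs.
#'
#' @param stack a [projection_stack()] covering at least 180 degrees.
#' @param angular_tol_deg tolerance for matching conjugate angles.
#' @param upsample DFT upsampling factor (10 gives 0.1 px precision).
#' @param min_peak floor on the phase-correlation peak; if every pair falls
#'   below it the alignment signal is too weak and an error is raised.
#' @param max_offset_frac sanity bound: aggregated offsets beyond this
#'   fraction of the frame width are refused by [apply_cor_correction()].
#' @return An `alignment_result` list: `cor_offset_px` (median estimate),
#'   `per_pair_estimates` (data.frame of angle, estimate, peak correlation),
#'   `method = "phase_correlation"`.
#' @export
estimate_cor <- function(stack, angular_tol_deg = 1, upsample = 10L,
                         min_peak = 0.2, max_offset_frac = 0.25) {
  stopifnot(inherits(stack, "projection_stack"))
  ang <- stack$angles_deg %% 360
  pairs <- list()
  for (i in seq_along(ang)) {
    if (ang[i] >= 180) next
    target <- ang[i] + 180
    j <- which.min(abs(ang - target))
    if (abs(ang[j] - target) <= angular_tol_deg) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (length(pairs) == 0L)
    stop("no conjugate (theta, theta+180) frame pairs within ",
         angular_tol_deg, " degrees: cannot estimate center of rotation")
  W <- dim(stack$data)[2L]
  est <- vapply(pairs, function(p) {
    f1 <- stack$data[, , p[1L]]
    f2 <- stack$data[, W:1, p[2L]] # horizontal mirror of the conjugate
    pc <- phase_correlate(f1, f2, upsample)
    c(stack$angles_deg[p[1L]], -pc$shift[2L] / 2, pc$peak)
  }, numeric(3))
  res <- data.frame(angle_deg = est[1L, ], estimate_px = est[2L, ],
                    peak_correlation = pmin(pmax(est[3L, ], 0), 1))
  ok <- res$peak_correlation >= min_peak
  if (!any(ok))
    stop("alignment signal too weak: all phase-correlation peaks below ", min_peak)
  structure(list(cor_offset_px = median(res$estimate_px[ok]),
                 per_pair_estimates = res, method = "phase_correlation",
                 max_offset_px = max_offset_frac * W),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> cor_offset_px = %.3f (median of %d conjugate pairs, %s)\n",
              x$cor_offset_px, nrow(x$per_pair_estimates), x$method))
  invisible(x)
}

#' Shift a projection stack to center its rotation axis
#'
#' Translates every frame horizontally by minus the estimated
#' center-of-rotation offset using Fourier-domain sub-pixel interpolation
#' (exact for band-limited content; frames are assumed dark at the detector
#' edges, as OPT specimens fit the field of view). A zero offset returns the
#' stack bit-identically. The stack metadata is updated to
#' `cor_offset_px = 0`.
#'
#' @param stack a [projection_stack()].
#' @param result an [estimate_cor()] result, or a single number of pixels.
#' @return The corrected [projection_stack()].
#' @export
apply_cor_correction <- function(stack, result) {
  stopifnot(inherits(stack, "projection_stack"))
  offset <- if (inherits(result, "alignment_result")) result$cor_offset_px else result
  bound <- if (inherits(result, "alignment_result")) result$max_offset_px
           else dim(stack$data)[2L] / 4
  if (abs(offset) >= bound)
    stop(sprintf("refusing center-of-rotation correction of %.2f px (sanity bound %.1f px)",
                 offset, bound))
  out <- stack
  if (offset != 0) {
    d <- dim(stack$data)
    W <- d[2L]
    k <- c(0:floor(W / 2), -(ceiling(W / 2 - 1):1))
    if (W %% 2 == 0) k[W / 2 + 1L] <- 0 # kill the ambiguous Nyquist term
    phase <- exp(2i * pi * k * offset / W)
    for (i in seq_len(d[3L])) {
      fr <- t(stack$data[, , i]) # columns of fr = detector rows
      sh <- Re(mvfft(mvfft(fr) * phase, inverse = TRUE)) / W
      out$data[, , i] <- t(sh)
    }
  }
  out$cor_offset_px <- 0
  out$meta$cor_correction_px <- offset
  out
}
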