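#' Preprocessing parameters
#'
#' Projection-domain conditioning applied before alignment and
#' reconstruction: percentile range cutting (to raise the
#' signal-to-background ratio) and per-frame contrast-limited adaptive
#' histogram equalization (CLAHE) on a tile grid.
#'
#' @param clip_lo_percentile,clip_hi_percentile global stack percentiles to
#'   clip at before rescaling to `[0, 1]`. Defaults 1 and 99.5 remove hot
#'   pixels without flattening islet signal.
#' @param clahe_tile tile size in pixels `(rows, cols)`; the classic 32 x 32
#'   tiling is the default.
#' @param clahe_clip_limit histogram clip limit as a fraction of the pixels
#'   per tile (0.01 is a mild, conventional limit).
#' @param clahe_enabled logical; CLAHE is non-linear, so quantitative
#'   reconstructions can be run from range-cut-only projections by disabling
#'   it (see [pipeline_config()]).
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(clip_lo_percentile = 1, clip_hi_percentile = 99.5,
                              clahe_tile = c(32L, 32L), clahe_clip_limit = 0.01,
                              clahe_enabled = TRUE) {
  stopifnot(clip_lo_percentile >= 0, clip_lo_percentile < 100,
            clip_hi_percentile > clip_lo_percentile, clip_hi_percentile <= 100,
            length(clahe_tile) == 2L, all(clahe_tile >= 1L),
            clahe_clip_limit > 0)
  structure(list(clip_lo_percentile = clip_lo_percentile,
                 clip_hi_percentile = clip_hi_percentile,
                 clahe_tile = as.integer(clahe_tile),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_enabled = isTRUE(clahe_enabled)),
            class = "preprocess_params")
}

#' Cut the pixel value range of a projection stack
#'
#' Clips the stack at global low/high percentiles (computed over all frames
#' jointly) and rescales linearly to `[0, 1]`. The mapping is monotone on the
#' non-clipped range. A constant stack (degenerate percentiles) yields an
#' all-zero stack with a warning rather than an error.
#'
#' @param stack a [projection_stack()].
#' @param params a [preprocess_params()].
#' @return The range-cut [projection_stack()].
#' @export
cut_range <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "projection_stack"))
  p <- quantile(stack$data,
                c(params$clip_lo_percentile, params$clip_hi_percentile) / 100,
                names = FALSE)
  out <- stack
  if (p[2L] <= p[1L]) {
    warning("degenerate percentile range (stack constant?): returning all-zero stack")
    out$data[] <- 0
  } else {
    out$data <- pmin(pmax((stack$data - p[1L]) / (p[2L] - p[1L]), 0), 1)
  }
  out$meta$range_cut <- list(lo = p[1L], hi = p[2L],
                             percentiles = c(params$clip_lo_percentile,
                                             params$clip_hi_percentile))
  out
}

# Global histogram equalization with a clipped histogram: the 1x1-tile limit
# of CLAHE. clip_frac is the clip limit as a fraction of the pixel count.
clipped_global_equalize <- function(frame, clip_frac, bins = 256L) {
  n <- length(frame)
  idx <- pmin(pmax(floor(frame * bins) + 1L, 1L), bins)
  h <- tabulate(idx, nbins = bins)
  clip <- max(1, clip_frac * n)
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / bins
  cdf <- cumsum(h)
  map <- (cdf - cdf[1L]) / max(cdf[bins] - cdf[1L], .Machine$double.eps)
  matrix(map[idx], nrow(frame), ncol(frame))
}

#' Contrast-limited adaptive histogram equalization of a stack
#'
#' Applies CLAHE frame by frame (projections at different angles have
#' different content, so frames are equalized independently). Each frame is
#' partitioned into tiles of `clahe_tile` pixels; per-tile histograms are
#' clipped at the clip limit with the excess redistributed, and the per-tile
#' equalization mappings are bilinearly interpolated between tile centers.
#' The tile-grid machinery is EBImage's; frames whose size is not a multiple
#' of the tile are edge-padded and cropped back, and a tile grid that
#' degenerates to a single tile falls back to global clipped equalization.
#'
#' @param stack a [projection_stack()] with values in `[0, 1]`
#'   (run [cut_range()] first).
#' @param params a [preprocess_params()].
#' @return The equalized [projection_stack()], values in `[0, 1]`.
#' @export
apply_clahe <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "projection_stack"))
  rng <- range(stack$data)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("CLAHE expects values in [0, 1]; run cut_range() first")
  d <- dim(stack$data)
  tile <- params$clahe_tile
  if (tile[1L] > d[1L] || tile[2L] > d[2L])
    stop(sprintf("CLAHE tile (%d x %d) is larger than the frame (%d x %d)",
                 tile[1L], tile[2L], d[1L], d[2L]))
  out <- stack
  for (i in seq_len(d[3L]))
    out$data[, , i] <- clahe_frame(stack$data[, , i], tile, params$clahe_clip_limit)
  out$meta$clahe <- list(tile = tile, clip_limit = params$clahe_clip_limit)
  out
}

clahe_frame <- function(frame, tile, clip_frac, bins = 256L) {
  d <- dim(frame)
  ntile <- pmax(1L, as.integer(round(d / tile)))
  if (all(ntile == 1L))
    return(clipped_global_equalize(frame, clip_frac, bins))
  # EBImage needs >= 2 tiles per axis and dims divisible by the tile count;
  # pad by edge replication to the next workable size, then crop back.
  ntile <- pmax(ntile, 2L)
  padded_dim <- ntile * tile
  pad <- pmax(padded_dim - d, 0L)
  f <- frame
  if (pad[1L] > 0L) f <- rbind(f, f[rep(nrow(f), pad[1L]), , drop = FALSE])
  if (pad[2L] > 0L) f <- cbind(f, f[, rep(ncol(f), pad[2L]), drop = FALSE])
  # if the frame over-ran the padded grid (d > ntile*tile), grow the grid
  ntile <- as.integer(dim(f) / tile)
  if (any(dim(f) %% tile != 0L)) {
    extra <- tile - dim(f) %% tile
    extra[extra == tile] <- 0L
    if (extra[1L] > 0L) f <- rbind(f, f[rep(nrow(f), extra[1L]), , drop = FALSE])
    if (extra[2L] > 0L) f <- cbind(f, f[, rep(ncol(f), extra[2L]), drop = FALSE])
    ntile <- as.integer(dim(f) / tile)
  }
  eq <- EBImage::clahe(EBImage::Image(f), nx = ntile[1L], ny = ntile[2L],
                       bins = bins, limit = clip_frac * bins,
                       keep.range = FALSE)
  res <- EBImage::imageData(eq)[seq_len(d[1L]), seq_len(d[2L])]
  pmin(pmax(res, 0), 1)
}

#' Run the full projection-domain preprocessing
#'
#' [cut_range()] followed (optionally) by [apply_clahe()].
#'
#' @inheritParams cut_range
#' @return A preprocessed [projection_stack()].
#' @export
preprocess_stack <- function(stack, params = preprocess_params()) {
  out <- cut_range(stack, params)
  if (params$clahe_enabled) out <- apply_clahe(out, params)
  out
}
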