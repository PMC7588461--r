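# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs user
# reproducibility.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Fan a global seed out to per-stage seeds by a fixed affine derivation so
# stochastic stages are independently reproducible. Result stays below 2^31.
derive_seed <- function(seed, stage) {
  k <- sum(utf8ToInt(stage))
  as.integer((as.double(seed %% 2147483647L) * 69069 + k) %% 2147483647)
}

# Global Otsu threshold of a numeric vector, delegated to EBImage on the
# values rescaled to [0, 1]. Returns the threshold on the original scale.
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values for Otsu threshold")
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) return(lo)
  v01 <- (values - lo) / (hi - lo)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1L)),
                         range = c(0, 1), levels = levels)
  lo + thr01 * (hi - lo)
}

# Near-Gaussian 3D smoothing: three box-filter passes per axis (central
# limit of the uniform kernel), values outside the grid treated as zero.
# The box radius is chosen so the cascade's standard deviation matches
# sigma_vox. O(1) per voxel independent of sigma.
gaussian_blur3 <- function(arr, sigma_vox, passes = 3L) {
  d <- dim(arr)
  # per-pass variance of a box of radius r is r(r+1)/3
  r <- max(1L, round((sqrt(1 + 12 * sigma_vox^2 / passes) - 1) / 2))
  out <- cpp_box_blur_axis(as.double(arr), as.integer(d), r, 0L, passes)
  out <- cpp_box_blur_axis(out, as.integer(d), r, 1L, passes)
  out <- cpp_box_blur_axis(out, as.integer(d), r, 2L, passes)
  dim(out) <- d
  out
}

# Offsets of a voxel ball of the given radius, as a k x 3 integer matrix of
# (dy, dx, dz), for morphological dilation/erosion.
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r, dz = -r:r)
  keep <- g$dy^2 + g$dx^2 + g$dz^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

dilate3 <- function(mask, radius) {
  d <- dim(mask)
  out <- cpp_dilate3d(as.logical(mask), as.integer(d), ball_offsets(radius))
  dim(out) <- d
  out
}

erode3 <- function(mask, radius) {
  d <- dim(mask)
  out <- !cpp_dilate3d(!as.logical(mask), as.integer(d), ball_offsets(radius))
  dim(out) <- d
  out
}

# Morphological closing (dilate then erode) with a ball element.
close3 <- function(mask, radius) erode3(dilate3(mask, radius), radius)

# Fill interior cavities: background components (6-connected) not reaching
# the volume border are inside the specimen and become foreground.
fill_holes3 <- function(mask) {
  d <- dim(mask)
  bg <- cpp_label3d(!mask, as.integer(d), 6L)
  dim(bg) <- d
  border <- unique(c(bg[c(1L, d[1L]), , ], bg[, c(1L, d[2L]), ],
                     bg[, , c(1L, d[3L])]))
  border <- border[border > 0L]
  out <- mask | !(array(bg %in% c(0L, border), dim = d))
  dim(out) <- d
  out
}

md5_of <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(object, f, version = 2L)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
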