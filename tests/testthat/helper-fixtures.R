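# Shared fixtures, memoised so expensive phantoms/reconstructions are built
# once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 64^3 phantom with a modest islet load: the workhorse for alignment and
# segmentation tests.
small_phantom <- function() fixture("small_phantom", function() {
  generate_phantom(phantom_spec(shape_vox = c(64L, 64L, 64L), n_islets = 16L,
                                islet_diameter_log_mu = log(90),
                                islet_diameter_log_sigma = 0.25, seed = 3L))
})

small_stack <- function() fixture("small_stack", function() {
  forward_project(small_phantom()$volume,
                  acquisition_spec(n_angles = 120L, angular_range_deg = 360))
})

# noise-free reconstruction of the small phantom (aligned by construction)
small_reconstruction <- function() fixture("small_reconstruction", function() {
  reconstruct_volume(small_stack())
})

# cylinder (rotationally symmetric about z) phantom volume
cylinder_volume <- function(W = 48L, nz = 6L, radius = W / 5) {
  ctr <- (W + 1) / 2
  r2 <- outer((seq_len(W) - ctr)^2, (seq_len(W) - ctr)^2, `+`)
  v <- array(0, c(W, W, nz))
  for (k in seq_len(nz)) v[, , k][r2 <= radius^2] <- 1
  opt_volume(v, 10)
}

# volume with one bright voxel
point_volume <- function(W = 64L, nz = 5L, y, x, z = ceiling(nz / 2)) {
  v <- array(0, c(W, W, nz))
  v[y, x, z] <- 1
  opt_volume(v, 10)
}

# integer circular shift of every frame along the detector axis: the exact
# horizontal translation used by equivariance properties
shift_stack_columns <- function(stack, k) {
  W <- dim(stack$data)[2L]
  idx <- ((seq_len(W) - 1L - k) %% W) + 1L
  out <- stack
  out$data <- stack$data[, idx, , drop = FALSE]
  out
}

# paint an axis-aligned box of the given value into an array
paint_box <- function(arr, y, x, z, value = 1) {
  arr[y, x, z] <- value
  arr
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
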