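test_that("empty phantom is a constant-intensity parenchyma block", {
  ph <- generate_phantom(phantom_spec(shape_vox = c(32L, 32L, 32L),
                                      n_islets = 0L, seed = 1L))
  expect_equal(nrow(ph$islet_table), 0L)
  inside <- ph$tissue_mask
  expect_true(all(ph$volume$data[inside] == 1))
  expect_true(all(ph$volume$data[!inside] == 0))
  expect_setequal(unique(as.vector(ph$label_volume)), c(0L, 1L))
})

test_that("identical seeds give bit-identical phantoms, different seeds differ", {
  spec <- phantom_spec(shape_vox = c(48L, 48L, 48L), n_islets = 12L,
                       islet_diameter_log_mu = log(60),
                       islet_diameter_log_sigma = 0.3, seed = 7L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$label_volume, b$label_volume)
  expect_identical(a$islet_table, b$islet_table)
  c <- generate_phantom(phantom_spec(shape_vox = c(48L, 48L, 48L),
                                      n_islets = 12L,
                                      islet_diameter_log_mu = log(60),
                                      islet_diameter_log_sigma = 0.3, seed = 8L))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("islet diameters follow the prescribed lognormal law", {
  ph <- generate_phantom(phantom_spec(shape_vox = c(160L, 160L, 160L),
                                      n_islets = 50L,
                                      islet_diameter_log_mu = log(100),
                                      islet_diameter_log_sigma = 0.4,
                                      seed = 11L))
  expect_equal(nrow(ph$islet_table), 50L)
  ks <- suppressWarnings(
    stats::ks.test(ph$islet_table$diameter_um, stats::plnorm,
                   meanlog = log(100), sdlog = 0.4))
  expect_gt(ks$p.value, 0.01)
})

test_that("ground-truth labels and analytic volumes are consistent", {
  ph <- small_phantom()
  tab <- ph$islet_table
  expect_equal(max(ph$label_volume), nrow(tab) + 3L)
  vs <- ph$volume$voxel_size_um
  for (i in seq_len(nrow(tab))) {
    count <- sum(ph$label_volume == i + 3L)
    r <- tab$diameter_um[i] / vs / 2
    analytic <- 4 / 3 * pi * r^3
    shell <- 4 * pi * (r + 0.87)^2 * 1.74 # one-voxel surface shell allowance
    expect_lt(abs(count - analytic), shell)
  }
})

test_that("placement failure reports the crowding parameters", {
  expect_error(
    generate_phantom(phantom_spec(shape_vox = c(48L, 48L, 48L), n_islets = 80L,
                                  islet_diameter_log_mu = log(80),
                                  islet_diameter_log_sigma = 0.1, seed = 2L)),
    "non-overlapping islets")
})

test_that("projections of a rotationally symmetric cylinder are identical", {
  # axis-aligned rotations resample the grid exactly: frames agree to
  # numerical precision even for a hard-edged disc
  st4 <- forward_project(cylinder_volume(), acquisition_spec(n_angles = 4L))
  ref <- st4$data[, , 1L]
  for (i in 2:4)
    expect_lt(max(abs(st4$data[, , i] - ref)), 1e-6 * max(ref))
  # at arbitrary angles a smooth radial profile agrees within the bilinear
  # interpolation tolerance
  W <- 48L
  ctr <- (W + 1) / 2
  r2 <- outer((seq_len(W) - ctr)^2, (seq_len(W) - ctr)^2, `+`)
  smooth <- array(exp(-r2 / (2 * 8^2)), c(W, W, 4L))
  st <- forward_project(opt_volume(smooth, 10), acquisition_spec(n_angles = 16L))
  ref <- st$data[, , 1L]
  for (i in 2:16)
    expect_lt(max(abs(st$data[, , i] - ref)), 0.03 * max(ref))
})

test_that("0/180 degree frames obey parallel-beam conjugate symmetry", {
  for (seed in c(3L, 9L, 21L)) {
    ph <- generate_phantom(phantom_spec(shape_vox = c(48L, 48L, 48L),
                                        n_islets = 6L,
                                        islet_diameter_log_mu = log(70),
                                        islet_diameter_log_sigma = 0.2,
                                        seed = seed))
    st <- forward_project(ph$volume, acquisition_spec(n_angles = 10L))
    W <- dim(st$data)[2L]
    f0 <- st$data[, , 1L]
    f180 <- st$data[, W:1, 6L] # angle index 6 is 180 degrees
    expect_lt(max(abs(f0 - f180)), 1e-9 * max(f0))
  }
})

test_that("a point projects to the analytic detector column", {
  W <- 64L
  cu <- (W + 1) / 2
  vol <- point_volume(W, 5L, y = 32L, x = 33L) # on-axis within half a pixel
  for (co in c(0, 5)) {
    st <- forward_project(vol, acquisition_spec(n_angles = 8L, cor_offset_px = co))
    for (i in seq_len(8L)) {
      peak <- which.max(st$data[3L, , i])
      expect_lt(abs(peak - (cu + co)), 1.6)
    }
  }
})

test_that("line integrals conserve total intensity at every angle", {
  ph <- small_phantom()
  st <- small_stack()
  total <- sum(ph$volume$data)
  sums <- apply(st$data, 3L, sum)
  expect_true(all(abs(sums - total) / total < 0.01))
})

test_that("acquisition noise is seeded and reproducible", {
  vol <- small_phantom()$volume
  acq <- acquisition_spec(n_angles = 6L, noise_model = "gaussian",
                          noise_scale = 0.05, seed = 13L)
  a <- forward_project(vol, acq)
  b <- forward_project(vol, acq)
  expect_identical(a$data, b$data)
  acq2 <- acquisition_spec(n_angles = 6L, noise_model = "poisson_gaussian",
                           noise_scale = 0.02, seed = 13L)
  c <- forward_project(vol, acq2)
  expect_false(identical(a$data, c$data))
  expect_identical(c$data, forward_project(vol, acq2)$data)
})

test_that("anisotropic geometry is refused by the projector", {
  v <- opt_volume(array(1, c(32L, 32L, 8L)), 10)
  expect_error(forward_project(opt_volume(array(1, c(32L, 24L, 8L)), 10),
                               acquisition_spec(n_angles = 4L)),
               "square")
  expect_error(opt_volume(array(1, c(8, 8, 8)), c(5, 5, 10)),
               "anisotropic|single positive")
  expect_silent(forward_project(v, acquisition_spec(n_angles = 4L)))
})

test_that("tumor ellipsoid is strictly darker and labeled 2", {
  ph <- generate_phantom(phantom_spec(
    shape_vox = c(48L, 48L, 48L), n_islets = 0L,
    tumor = list(center_vox = c(24, 24, 24), semi_axes_vox = c(10, 8, 8),
                 intensity_factor = 0.4), seed = 4L))
  tum <- ph$label_volume == 2L
  expect_true(sum(tum) > 0)
  expect_true(all(ph$volume$data[tum] == 0.4))
  expect_error(phantom_spec(tumor = list(center_vox = c(1, 1, 1),
                                         semi_axes_vox = c(2, 2, 2),
                                         intensity_factor = 1)),
               "intensity_factor")
})
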