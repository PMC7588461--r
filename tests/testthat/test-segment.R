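test_that("tissue mask recovers the phantom support from a reconstruction", {
  ph <- small_phantom()
  rec <- small_reconstruction()
  m <- tissue_mask(rec)
  expect_gt(dice_coef(m, ph$tissue_mask), 0.95)
})

test_that("an empty volume raises 'no tissue detected'", {
  expect_error(tissue_mask(opt_volume(array(0, c(16L, 16L, 16L)), 10)),
               "no tissue")
})

test_that("the tissue mask is invariant to linear intensity rescaling", {
  rec <- small_reconstruction()
  m1 <- tissue_mask(rec)
  m2 <- tissue_mask(opt_volume(3.7 * rec$data + 0.5, rec$voxel_size_um))
  expect_identical(m1, m2)
})

test_that("percentile baseline zeroes a constant volume inside the mask", {
  v <- opt_volume(array(4, c(24L, 24L, 24L)), 10)
  mask <- array(TRUE, dim = dim(v$data))
  out <- subtract_baseline(v, segmentation_params(
    baseline_method = "percentile_constant"), mask)
  expect_true(all(out$data == 0))
})

test_that("gaussian background preserves a bright sphere on a flat field", {
  d <- c(64L, 64L, 64L)
  v <- array(1, d)
  ctr <- c(32, 32, 32)
  r2 <- outer(outer((seq_len(d[1L]) - ctr[1L])^2,
                    (seq_len(d[2L]) - ctr[2L])^2, `+`),
              (seq_len(d[3L]) - ctr[3L])^2, `+`)
  v[r2 <= 5^2] <- 3
  vol <- opt_volume(v, 10)
  mask <- array(TRUE, dim = d)
  out <- subtract_baseline(vol, segmentation_params(baseline_sigma_um = 200),
                           mask)
  peak <- max(out$data)
  expect_gt(peak, 0.9 * 2) # sphere amplitude 2 preserved within 10%
  background <- out$data[r2 > 12^2]
  expect_lt(max(background), 0.05 * peak)
  expect_true(all(out$data >= 0))
  expect_error(subtract_baseline(vol, segmentation_params(baseline_sigma_um = 15),
                                 mask),
               "under 2 voxels")
})

test_that("noise-free phantom islets are recovered one-to-one", {
  ph <- generate_phantom(phantom_spec(shape_vox = c(96L, 96L, 96L),
                                      n_islets = 25L, seed = 17L))
  sp <- segmentation_params()
  mask <- ph$tissue_mask
  bs <- subtract_baseline(ph$volume, sp, mask)
  lv <- label_islets(bs, sp, mask)
  expect_equal(max(lv$labels), 25L)
  rec <- measure_islets(lv, ph$volume)
  truth <- ph$islet_table
  for (i in seq_len(nrow(rec))) {
    dists <- sqrt((truth$cy - rec$centroid_y[i])^2 +
                  (truth$cx - rec$centroid_x[i])^2 +
                  (truth$cz - rec$centroid_z[i])^2)
    expect_lt(min(dists), 2)
  }
})

test_that("the voxel number filter is exact at its boundary", {
  d <- c(24L, 24L, 24L)
  v <- array(0, d)
  v[2:4, 2:4, 2:4] <- 10          # 27 voxels: exactly min_voxels
  v[10:12, 10:12, 10:12] <- 10    # 27 voxels minus one corner = 26
  v[12L, 12L, 12L] <- 0
  lv <- label_islets(opt_volume(v, 10),
                     segmentation_params(min_voxels = 27L, border_exclude = FALSE),
                     array(TRUE, dim = d))
  expect_equal(max(lv$labels), 1L)
  expect_equal(sum(lv$labels > 0L), 27L)
})

test_that("corner-touching blobs follow the declared connectivity", {
  d <- c(16L, 16L, 16L)
  v <- array(0, d)
  v[3:5, 3:5, 3:5] <- 1
  v[6:8, 6:8, 6:8] <- 1 # shares only the corner voxel pair (5,5,5)-(6,6,6)
  mask <- array(TRUE, dim = d)
  lv26 <- label_islets(opt_volume(v, 10),
                       segmentation_params(min_voxels = 1L, connectivity = 26L,
                                           border_exclude = FALSE), mask)
  lv6 <- label_islets(opt_volume(v, 10),
                      segmentation_params(min_voxels = 1L, connectivity = 6L,
                                          border_exclude = FALSE), mask)
  expect_equal(max(lv26$labels), 1L)
  expect_equal(max(lv6$labels), 2L)
})

test_that("hair-like components are removed, compact ones retained", {
  d <- c(72L, 72L, 72L)
  v <- array(0, d)
  v[10L, 10L, 5:64] <- 5          # 1 x 1 x 60 hair, elongation 60
  v[30:36, 30:36, 30:36] <- 5     # compact cube, elongation 1
  lv <- label_islets(opt_volume(v, 10),
                     segmentation_params(min_voxels = 20L, border_exclude = FALSE),
                     array(TRUE, dim = d))
  expect_equal(max(lv$labels), 2L)
  out <- remove_artifacts(lv, segmentation_params(border_exclude = FALSE))
  expect_equal(max(out$labels), 1L)
  st <- aftomo:::cpp_label_stats(out$labels, as.integer(d), numeric(0))
  expect_equal(as.integer(st$count), 343L) # the 7^3 cube survived
})

test_that("injected hairs do not survive quantification on a phantom", {
  ph <- generate_phantom(phantom_spec(shape_vox = c(96L, 96L, 96L),
                                      n_islets = 12L, seed = 23L))
  v <- ph$volume$data
  set.seed(23)
  placed <- 0L
  while (placed < 5L) { # 2x2x40 bars: length/width = 20
    y <- sample(20:70, 1L)
    x <- sample(20:70, 1L)
    z0 <- sample(10:40, 1L)
    # a hair crossing an islet would merge with it; keep them distinct objects
    if (any(ph$label_volume[y:(y + 1L), x:(x + 1L), z0:(z0 + 39L)] > 3L)) next
    v[y:(y + 1L), x:(x + 1L), z0:(z0 + 39L)] <- 3 # as bright as the islets
    placed <- placed + 1L
  }
  vol <- opt_volume(v, ph$volume$voxel_size_um)
  sp <- segmentation_params()
  bs <- subtract_baseline(vol, sp, ph$tissue_mask)
  lv <- remove_artifacts(label_islets(bs, sp, ph$tissue_mask), sp)
  rec <- measure_islets(lv, vol)
  truth <- ph$islet_table
  expect_equal(nrow(rec), 12L)
  for (i in seq_len(nrow(rec))) {
    dists <- sqrt((truth$cy - rec$centroid_y[i])^2 +
                  (truth$cx - rec$centroid_x[i])^2 +
                  (truth$cz - rec$centroid_z[i])^2)
    expect_lt(min(dists), 2)
  }
})

test_that("every retained component satisfies the voxel number filter", {
  ph <- small_phantom()
  sp <- segmentation_params(min_voxels = 40L)
  bs <- subtract_baseline(ph$volume, sp, ph$tissue_mask)
  lv <- label_islets(bs, sp, ph$tissue_mask)
  counts <- tabulate(lv$labels[lv$labels > 0L])
  expect_true(all(counts >= 40L))
  # scale invariance of the segmentation
  bs2 <- bs
  bs2$data <- bs2$data * 12
  bs2$meta$background_sigma <- bs2$meta$background_sigma * 12
  bs2$meta$background_median <- bs2$meta$background_median * 12
  lv2 <- label_islets(bs2, sp, ph$tissue_mask)
  expect_identical(lv$labels, lv2$labels)
})

test_that("a low-AF ellipsoid is delineated and a clean volume warns", {
  spec <- phantom_spec(shape_vox = c(64L, 64L, 48L), n_islets = 0L,
                       tumor = list(center_vox = c(36, 30, 24),
                                    semi_axes_vox = c(14, 11, 10),
                                    intensity_factor = 0.4), seed = 31L)
  ph <- generate_phantom(spec)
  truth <- ph$label_volume == 2L
  m <- ph$tissue_mask
  got <- delineate_low_af_region(ph$volume, segmentation_params(), m)
  expect_gt(dice_coef(got, truth), 0.9)
  expect_lt(abs(sum(got) / sum(truth) - 1), 0.1)
  clean <- generate_phantom(phantom_spec(shape_vox = c(48L, 48L, 48L),
                                         n_islets = 0L, seed = 1L))
  expect_warning(
    empty <- delineate_low_af_region(clean$volume, segmentation_params(),
                                     clean$tissue_mask),
    "empty mask")
  expect_false(any(empty))
})

test_that("recovered tumor volume shrinks as contrast fades", {
  vols <- vapply(c(0.3, 0.5, 0.7), function(f) {
    ph <- generate_phantom(phantom_spec(
      shape_vox = c(64L, 64L, 48L), n_islets = 0L,
      tumor = list(center_vox = c(36, 30, 24), semi_axes_vox = c(14, 11, 10),
                   intensity_factor = f), seed = 31L))
    got <- suppressWarnings(
      delineate_low_af_region(ph$volume, segmentation_params(), ph$tissue_mask))
    sum(got)
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
  expect_gt(vols[1L], 0)
})
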