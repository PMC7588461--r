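box_label_volume <- function(d, boxes, vs = 10) {
  lab <- array(0L, dim = d)
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    lab[b[[1L]], b[[2L]], b[[3L]]] <- i
  }
  label_volume(lab, vs)
}

test_that("measured extents, diameters and volumes match closed forms", {
  d <- c(24L, 24L, 24L)
  lv <- box_label_volume(d, list(list(2:4, 2:4, 2:4),      # 3x3x3 cube
                                 list(10L, 12:13, 15:17))) # 1x2x3 box
  vol <- opt_volume(array(1, d), 10)
  rec <- measure_islets(lv, vol)
  expect_equal(rec$voxel_count, c(27L, 6L))
  expect_equal(rec$volume_um3, c(27000, 6000))
  expect_equal(rec$extent_y_um[1L], 30)
  expect_equal(rec$mean_diameter_um[1L], 30)
  # extents (10, 20, 30) um average to exactly 20 um
  expect_equal(sort(c(rec$extent_y_um[2L], rec$extent_x_um[2L],
                      rec$extent_z_um[2L])), c(10, 20, 30))
  expect_identical(rec$mean_diameter_um[2L], 20)
})

test_that("a voxelized sphere measures near its analytic size", {
  d <- c(32L, 32L, 32L)
  ctr <- c(16.3, 15.8, 16.1)
  r2 <- outer(outer((seq_len(d[1L]) - ctr[1L])^2,
                    (seq_len(d[2L]) - ctr[2L])^2, `+`),
              (seq_len(d[3L]) - ctr[3L])^2, `+`)
  lab <- array(0L, dim = d)
  lab[r2 <= 6^2] <- 1L
  lv <- label_volume(lab, 10)
  rec <- measure_islets(lv, opt_volume(array(1, d), 10))
  expect_lt(abs(rec$mean_diameter_um - 120), 10)
  expect_lt(abs(rec$volume_um3 / (pi / 6 * 120^3) - 1), 0.15)
})

test_that("geometry mismatches are refused", {
  lv <- box_label_volume(c(16L, 16L, 16L), list(list(2:3, 2:3, 2:3)))
  expect_error(measure_islets(lv, opt_volume(array(1, c(16L, 16L, 8L)), 10)),
               "different grids")
  expect_error(measure_islets(lv, opt_volume(array(1, c(16L, 16L, 16L)), 5)),
               "voxel size")
})

test_that("per-object intensity sums equal a brute-force voxel loop", {
  set.seed(12)
  d <- c(20L, 20L, 20L)
  ph <- generate_phantom(phantom_spec(shape_vox = c(48L, 48L, 48L),
                                      n_islets = 8L,
                                      islet_diameter_log_mu = log(60),
                                      islet_diameter_log_sigma = 0.2,
                                      seed = 41L))
  lab <- ph$label_volume
  lab[lab <= 3L] <- 0L
  lab[lab > 3L] <- lab[lab > 3L] - 3L
  lv <- label_volume(lab, ph$volume$voxel_size_um)
  intensity <- opt_volume(array(runif(length(lab)), dim = dim(lab)),
                          ph$volume$voxel_size_um)
  got <- per_object_intensity_stats(lv, intensity)
  for (l in seq_len(max(lab))) {
    member <- which(lab == l)
    acc <- 0 # brute-force voxel loop in plain double accumulation
    for (i in member) acc <- acc + intensity$data[i]
    expect_identical(got$intensity_sum[l], acc)
    expect_identical(got$intensity_max[l], max(intensity$data[member]))
  }
  # locality: editing one object's voxels leaves the others untouched
  intensity2 <- intensity
  intensity2$data[lab == 1L] <- 99
  got2 <- per_object_intensity_stats(lv, intensity2)
  expect_identical(got2$intensity_sum[-1L], got$intensity_sum[-1L])
  # constant intensity times voxel count, exactly
  const <- opt_volume(array(2.5, dim = dim(lab)), ph$volume$voxel_size_um)
  gotc <- per_object_intensity_stats(lv, const)
  expect_equal(gotc$intensity_sum, 2.5 * tabulate(lab[lab > 0L]))
})

test_that("maximum intensity projection obeys max semantics", {
  v <- array(0, c(8L, 9L, 10L))
  v[3L, 4L, 5L] <- 7
  m <- mip(opt_volume(v, 10), "z")
  expect_equal(dim(m), c(8L, 9L))
  expect_equal(which(m == 7, arr.ind = TRUE)[1L, ], c(row = 3L, col = 4L))
  expect_equal(sum(m > 0), 1L)
  set.seed(13)
  v <- array(runif(8 * 9 * 10), c(8L, 9L, 10L))
  base <- mip(v, "y")
  expect_identical(mip(pmax(v, 0.5 * v), "y"), base)
  for (k in seq_len(10L)) expect_true(all(mip(v, "z") >= v[, , k]))
})

test_that("size categories are half-open and conserve counts", {
  rec <- data.frame(mean_diameter_um = c(20, 20, 70),
                    volume_um3 = c(1, 1, 10))
  d <- size_distribution(rec, c(0, 50, 100))
  expect_equal(d$counts, c(2L, 1L))
  expect_equal(d$fractions, c(2 / 3, 1 / 3))
  expect_equal(sum(d$counts), d$n_total)
  edge <- size_distribution(data.frame(mean_diameter_um = 50, volume_um3 = 1),
                            c(0, 50, 100))
  expect_equal(edge$counts, c(0L, 1L)) # edge value falls in the upper bin
  expect_error(size_distribution(data.frame(mean_diameter_um = 120,
                                            volume_um3 = 1), c(0, 50, 100)),
               "outside")
  # permutation invariance
  set.seed(14)
  rec2 <- data.frame(mean_diameter_um = runif(60, 5, 95),
                     volume_um3 = runif(60))
  a <- size_distribution(rec2, seq(0, 100, 20))
  b <- size_distribution(rec2[sample.int(60), ], seq(0, 100, 20))
  expect_identical(a$counts, b$counts)
  expect_equal(sum(a$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(a$volume_um3), sum(rec2$volume_um3))
})

test_that("distribution comparison reports exact closed-form statistics", {
  self <- size_distribution(data.frame(mean_diameter_um = c(10, 10, 60),
                                       volume_um3 = c(1, 1, 1)), c(0, 50, 100))
  r <- compare_to_reference(self, self)
  expect_true(all(r$per_category$fraction_diff == 0))
  expect_identical(r$tv_distance, 0)
  expect_identical(r$chisq, 0)
  a <- size_distribution(data.frame(mean_diameter_um = rep(10, 10),
                                    volume_um3 = rep(1, 10)), c(0, 50, 100))
  b <- size_distribution(data.frame(mean_diameter_um = rep(60, 10),
                                    volume_um3 = rep(1, 10)), c(0, 50, 100))
  expect_identical(compare_to_reference(a, b)$tv_distance, 1)
  obs <- size_distribution(data.frame(mean_diameter_um = c(rep(10, 30), rep(60, 70)),
                                      volume_um3 = rep(1, 100)), c(0, 50, 100))
  ref <- obs
  ref$fractions <- c(0.5, 0.5)
  cmp <- compare_to_reference(obs, ref)
  expect_identical(cmp$chisq, 16)
  expect_identical(cmp$dof, 1L)
  wrong <- size_distribution(data.frame(mean_diameter_um = 10, volume_um3 = 1),
                             c(0, 25, 100))
  expect_error(compare_to_reference(obs, wrong), "different category edges")
})

test_that("exported statistics round-trip exactly, including a 7034-row table", {
  dir <- withr::local_tempdir()
  empty <- measure_islets(box_label_volume(c(8L, 8L, 8L), list()),
                          opt_volume(array(1, c(8L, 8L, 8L)), 10))
  export_statistics(empty, dir = dir)
  got <- read.csv(file.path(dir, "islets.csv"))
  expect_equal(nrow(got), 0L)
  expect_identical(names(got), names(empty))
  set.seed(15)
  n <- 7034L
  big <- data.frame(label_id = seq_len(n),
                    voxel_count = sample.int(5000L, n, replace = TRUE),
                    volume_um3 = stats::rlnorm(n, 13, 1),
                    extent_y_um = runif(n, 20, 400),
                    extent_x_um = runif(n, 20, 400),
                    extent_z_um = runif(n, 20, 400),
                    mean_diameter_um = runif(n, 20, 390),
                    centroid_y = runif(n, 1, 192),
                    centroid_x = runif(n, 1, 192),
                    centroid_z = runif(n, 1, 192),
                    intensity_sum = stats::rlnorm(n, 9, 2))
  dist <- size_distribution(big, seq(0, 400, 25))
  export_statistics(big, dist, dir = dir)
  back <- read.csv(file.path(dir, "islets.csv"))
  expect_equal(nrow(back), n)
  for (col in names(big)) expect_identical(back[[col]], big[[col]], label = col)
  dd <- read.csv(file.path(dir, "distribution.csv"))
  expect_identical(as.integer(dd$count), dist$counts)
})

test_that("voxel counts are conserved between labels and records", {
  ph <- small_phantom()
  sp <- segmentation_params()
  bs <- subtract_baseline(ph$volume, sp, ph$tissue_mask)
  lv <- label_islets(bs, sp, ph$tissue_mask)
  rec <- measure_islets(lv, ph$volume)
  expect_identical(sum(rec$voxel_count), sum(lv$labels > 0L))
})

test_that("reference distributions load from CSV and compare cleanly", {
  path <- system.file("extdata", "synthetic_reference_distribution.csv",
                      package = "aftomo")
  ref <- read_reference_distribution(path)
  expect_s3_class(ref, "size_distribution")
  expect_length(ref$fractions, 16L)
  expect_equal(sum(ref$fractions), 1, tolerance = 1e-9)
  set.seed(18)
  rec <- data.frame(mean_diameter_um = pmin(stats::rlnorm(300, log(110), 0.45), 399),
                    volume_um3 = stats::rlnorm(300, 13, 1))
  cmp <- compare_to_reference(size_distribution(rec, seq(0, 400, 25)), ref)
  expect_lt(cmp$tv_distance, 0.2) # same law, so the distributions are close
  expect_gte(cmp$chisq, 0)
  # non-contiguous reference bins are rejected
  bad <- tempfile(fileext = ".csv")
  writeLines(c("category_lo_um,category_hi_um,fraction",
               "0,50,0.5", "60,100,0.5"), bad)
  expect_error(read_reference_distribution(bad), "contiguous")
})
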