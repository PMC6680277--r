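test_that("generators are bit-reproducible under (seed, parameters)", {
  sp <- phantom_spec(shape = c(12L, 20L, 20L), noise_sigma = 200, seed = 5)
  expect_identical(make_calibration_phantom(sp)$data,
                   make_calibration_phantom(sp)$data)
  f1 <- make_foam_phantom(sp, 0.4, 30)
  f2 <- make_foam_phantom(sp, 0.4, 30)
  expect_identical(f1$volume$data, f2$volume$data)
  expect_identical(f1$ground_truth$tissue_mask, f2$ground_truth$tissue_mask)
  # different seed changes the realization
  sp2 <- phantom_spec(shape = c(12L, 20L, 20L), noise_sigma = 200, seed = 6)
  expect_false(identical(make_calibration_phantom(sp2)$data,
                         make_calibration_phantom(sp)$data))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_foam_phantom(sp, 0.4, 30)); after <- runif(3)
  expect_identical(before, after)
})

test_that("the calibration phantom has exactly two populations when noise-free", {
  sp <- phantom_spec(shape = c(8L, 24L, 24L), gray_air = 11, gray_wax = 99)
  ph <- make_calibration_phantom(sp)
  expect_setequal(unique(as.numeric(ph$data)), c(11, 99))
  expect_true(all(ph$data[attr(ph, "wax_mask")] == 99))
  expect_true(all(ph$data[attr(ph, "air_mask")] == 11))
  expect_error(phantom_spec(gray_air = 10, gray_wax = 5, gray_tissue = 20),
               "gray_air < gray_wax")
})

test_that("material levels of a noisy phantom are recovered within 3 SEM", {
  sp <- phantom_spec(shape = c(9L, 48L, 48L), gray_air = 100, gray_wax = 1000,
                     gray_tissue = 1200, noise_sigma = 5, seed = 31)
  ph <- make_calibration_phantom(sp)
  lv <- estimate_material_levels(ph)
  z <- sp$shape[1] %/% 2L + 1L
  expect_lt(abs(lv$i_air - 100), 3 * 5 / sqrt(sum(attr(ph, "air_mask")[z, , ])) + 0.5)
  expect_lt(abs(lv$i_wax - 1000), 3 * 5 / sqrt(sum(attr(ph, "wax_mask")[z, , ])) + 0.5)
})

test_that("geometric phantoms carry analytic ground truth", {
  sp <- phantom_spec(shape = c(24L, 24L, 24L), voxel_size_um = 2)
  gp <- make_geometric_phantom(sp, shapes = list(
    list(type = "ball", d = 9, center = c(6, 6, 12)),
    list(type = "rod", d = 5, axis = "z", center = c(17, 17))))
  gt <- gp$ground_truth
  expect_equal(gt$shape_thickness_um, c(18, 10))
  # volume fraction equals an exhaustive independent count (digital ball
  # of diameter d: centres strictly inside radius d/2)
  g <- expand.grid(z = 0:23, y = 0:23, x = 0:23)
  in_ball <- (g$x - 6)^2 + (g$y - 6)^2 + (g$z - 12)^2 < 4.5^2 - 1e-9
  in_rod <- (g$x - 17)^2 + (g$y - 17)^2 < 2.5^2 - 1e-9
  expect_equal(gt$true_volume_fraction, mean(in_ball | in_rod))
  expect_identical(gt$tissue_mask, array(in_ball | in_rod, c(24, 24, 24)))
  # slab across the full extent
  gs <- make_geometric_phantom(sp, shapes = list(
    list(type = "slab", t = 5, axis = "z", at = 10)))
  expect_equal(gs$ground_truth$shape_thickness_um, 10)
  expect_equal(sum(gs$ground_truth$tissue_mask), 5 * 24 * 24)
  # out-of-bounds shapes are refused
  expect_error(make_geometric_phantom(sp, shapes = list(
    list(type = "ball", d = 9, center = c(2, 6, 12)))), "outside")
})

test_that("foam phantoms hit the target volume fraction by construction", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), seed = 17)
  fm <- make_foam_phantom(sp, target_vf = 0.5, feature_scale_um = 25)
  n <- prod(sp$shape)
  # quantile construction: off by at most the rounding of k = round((1-vf)n)
  expect_lt(abs(fm$ground_truth$true_volume_fraction - 0.5), 1 / n)
  expect_equal(fm$ground_truth$true_volume_fraction,
               sum(fm$ground_truth$tissue_mask) / n)
  # volume values follow the mask exactly when noise-free
  expect_true(all(fm$volume$data[fm$ground_truth$tissue_mask] == sp$gray_tissue))
  expect_true(all(fm$volume$data[!fm$ground_truth$tissue_mask] == sp$gray_wax))
  expect_error(make_foam_phantom(sp, target_vf = 1), "strictly inside")
})

test_that("mean thickness grows with the foam feature scale", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), seed = 23)
  means <- vapply(c(20, 40, 80), function(fs) {
    fm <- make_foam_phantom(sp, target_vf = 0.4, feature_scale_um = fs)
    tm <- local_thickness(binary_volume(fm$ground_truth$tissue_mask,
                                        voxel_size_um = sp$voxel_size_um))
    mean(tm$thickness_um[fm$ground_truth$tissue_mask])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("block phantoms expose all three populations with exact masks", {
  sp <- phantom_spec(shape = c(16L, 48L, 48L), gray_air = 5, gray_wax = 50,
                     gray_tissue = 80, seed = 3)
  bp <- make_block_phantom(sp, target_vf = 0.4, air_margin = 8L, voi_margin = 16L)
  gt <- bp$ground_truth
  expect_true(all(bp$volume$data[gt$air_mask] == 5))
  expect_true(all(bp$volume$data[gt$wax_mask] == 50))
  expect_true(all(bp$volume$data[gt$tissue_mask] == 80))
  expect_equal(gt$true_volume_fraction, sum(gt$tissue_mask) / sum(gt$voi))
  expect_lt(abs(gt$true_volume_fraction - 0.4), 0.01)
  expect_error(make_block_phantom(sp, air_margin = 16L, voi_margin = 16L),
               "voi_margin")
})

test_that("histology pairs reduce to the palette-mapped slice at zero warp", {
  v <- banded_volume(c(24L, 40L, 40L), seed = 4)
  pl <- plane_spec(c(2, 2, 10), c(1, 0, 0), c(0, 1, 0), c(36, 36))
  hp <- make_histology_pair(v, pl, amplitude_px = 0, n_landmarks = 6L, seed = 2)
  s <- oblique_slice(v, pl)
  rngs <- range(s)
  sn <- (s - rngs[1]) / diff(rngs)
  expect_equal(hp$histology[, , 1], 1 - 0.25 * sn, tolerance = 1e-9)
  expect_equal(hp$ct_slice, s)
  # landmarks map to themselves under a zero field
  expect_equal(hp$ground_truth$landmarks_moving, hp$ground_truth$landmarks_target)
  # a known pure-translation field is recovered exactly at landmarks
  hp2 <- make_histology_pair(v, pl, amplitude_px = 2, n_landmarks = 8L, seed = 3)
  reg <- elastic_register(as_gray(hp2$histology), hp2$ct_slice,
                          hp2$ground_truth$landmarks_moving,
                          hp2$ground_truth$landmarks_target)
  mapped <- warp_forward(reg$warp, hp2$ground_truth$landmarks_moving)
  expect_lt(max(abs(mapped - hp2$ground_truth$landmarks_target)), 1e-6)
})
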