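test_that("plane fitting recovers exact and least-squares planes", {
  lm3 <- rbind(c(1, 1, 5), c(8, 2, 5), c(3, 9, 5))
  pl <- fit_plane(lm3)
  expect_equal(abs(attr(pl, "normal")), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$origin[3], 5, tolerance = 1e-12)
  expect_equal(attr(pl, "residuals"), rep(0, 3), tolerance = 1e-12)
  # four coplanar oblique points fit exactly
  n <- c(1, 2, 2) / 3
  u <- c(2, -1, 0) / sqrt(5)
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  pts <- t(sapply(list(c(0, 0), c(5, 1), c(2, 6), c(-3, 4)),
                  function(ab) c(10, 10, 10) + ab[1] * u + ab[2] * v))
  pl2 <- fit_plane(pts)
  expect_equal(attr(pl2, "residuals"), rep(0, 4), tolerance = 1e-9)
  # collinear points are degenerate
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))), "collinear")
  expect_error(landmark_set(matrix(0, 3, 2),
                            rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
})

test_that("landmark CSV files roundtrip with the required header", {
  tmp <- withr::local_tempdir()
  lms <- landmark_set(cbind(c(1, 40, 10), c(2, 5, 33)),
                      rbind(c(1, 2, 7), c(40, 5, 7.5), c(10, 33, 6.5)))
  p <- file.path(tmp, "lm.csv")
  write_landmarks(lms, p)
  expect_equal(readLines(p, n = 1), "\"x2d\",\"y2d\",\"x3d\",\"y3d\",\"z3d\"")
  r <- read_landmarks(p)
  expect_equal(r$p2d, lms$p2d)
  expect_equal(r$p3d, lms$p3d)
  writeLines(c("a,b", "1,2"), p)
  expect_error(read_landmarks(p), "header")
})

test_that("match_slice returns the stored slice for lattice-plane landmarks", {
  v <- banded_volume(c(20L, 40L, 40L), seed = 2)
  # rectangle with distinct x/y spreads: principal axes align with x and y
  lms <- landmark_set(cbind(c(2, 38, 2, 38), c(5, 5, 35, 35)),
                      rbind(c(2, 5, 6), c(38, 5, 6), c(2, 35, 6), c(38, 35, 6)))
  ms <- match_slice(v, lms, offsets = seq(-2, 2))
  expect_length(ms$candidates, 5)
  expect_equal(ms$offsets, seq(-2, 2))
  # the in-volume part of the slice matches the stored z = 6 slice
  pl <- ms$plane
  expect_equal(abs(attr(pl, "normal")), c(0, 0, 1), tolerance = 1e-9)
  full <- matrix(v$data[7, , ], 40)
  # locate the stored slice inside the (margin-padded) resample
  j0 <- round(1 - pl$origin[1]); i0 <- round(1 - pl$origin[2])
  sub <- ms$image[i0:(i0 + 39), j0:(j0 + 39)]
  expect_equal(sub, full, tolerance = 1e-9)
  # ncc ranking picks the matching slice
  ms2 <- match_slice(v, lms, offsets = seq(-2, 2), reference = ms$image)
  expect_equal(which.max(ms2$ncc), which(ms2$offsets == 0))
  far <- landmark_set(lms$p2d, lms$p3d + matrix(rep(c(0, 0, 1000), 4), 4, byrow = TRUE))
  expect_error(match_slice(v, far), "outside")
})

test_that("identity and translation landmark sets give the expected warps", {
  set.seed(15)
  img <- matrix(runif(35 * 30), 35, 30)
  src <- cbind(c(4, 25, 7, 20, 12), c(5, 6, 28, 25, 15))
  # identity pairs: warped image equals the moving image
  reg_id <- elastic_register(img, img, src, src)
  expect_equal(reg_id$warped, img, tolerance = 1e-9)
  rep_id <- registration_report(reg_id$warp, grid_step = 3)
  expect_equal(rep_id$max_displacement_px, 0, tolerance = 1e-8)
  # pure translation: the warp is that translation everywhere
  dst <- src + matrix(rep(c(10, -4), each = 5), 5)
  reg_tr <- elastic_register(img, img, src, dst)
  rep_tr <- registration_report(reg_tr$warp, grid_step = 3)
  expect_equal(rep_tr$mean_displacement_px, sqrt(116), tolerance = 1e-8)
  expect_equal(rep_tr$max_displacement_px, sqrt(116), tolerance = 1e-8)
  expect_equal(rep_tr$landmark_residuals_px, rep(0, 5), tolerance = 1e-8)
})

test_that("the spline interpolates landmarks and reproduces affine maps", {
  set.seed(16)
  src <- matrix(runif(24, 0, 60), 12, 2)
  # generic smooth deformation: landmark residuals vanish
  dst <- src + cbind(3 * sin(src[, 2] / 20), 2 * cos(src[, 1] / 15))
  reg <- elastic_register(matrix(0, 64, 64), matrix(0, 64, 64), src, dst)
  mapped <- warp_forward(reg$warp, src)
  expect_lt(max(sqrt(rowSums((mapped - dst)^2))), 1e-6)
  # affine pairs: radial coefficients vanish
  A <- matrix(c(1.05, 0.12, -0.08, 0.97), 2)
  dstA <- src %*% A + matrix(rep(c(2, -1), each = 12), 12)
  regA <- elastic_register(matrix(0, 64, 64), matrix(0, 64, 64), src, dstA)
  expect_lt(max(abs(regA$warp$fwd$w)), 1e-8)
  # collinear landmarks: affine-only fallback with a warning
  col_src <- cbind(1:4, 2 * (1:4))
  expect_warning(
    regC <- elastic_register(matrix(0, 16, 16), matrix(0, 16, 16),
                             col_src, col_src + 1),
    "collinear")
  expect_true(regC$warp$affine_only)
})

test_that("warping with reversed pairs approximately inverts the warp", {
  # smooth image, gentle deformation: the round trip is limited only by
  # interpolation blur
  g <- expand.grid(y = 0:47, x = 0:47)
  img <- matrix(0.5 + 0.4 * sin(g$x / 7) * cos(g$y / 9), 48, 48)
  src <- cbind(c(6, 40, 8, 42, 24, 24), c(6, 8, 40, 42, 12, 36))
  dst <- src + cbind(2 * sin(src[, 2] / 25), -2 * cos(src[, 1] / 25))
  fwd <- elastic_register(img, img, src, dst)
  back <- elastic_register(fwd$warped, img, dst, src)
  core <- 9:40
  expect_lt(mean(abs(back$warped[core, core] - img[core, core])), 0.02)
})

test_that("a generator-known smooth deformation is recovered below 1 px", {
  v <- banded_volume(seed = 1)
  pl <- plane_spec(c(4, 4, 20), c(1, 0, 0), c(0, 1, 0), c(56, 56))
  for (sd in c(1, 2, 3)) {
    hp <- make_histology_pair(v, pl, amplitude_px = 3, n_landmarks = 12L, seed = sd)
    mov <- as_gray(hp$histology)
    reg <- elastic_register(mov, hp$ct_slice,
                            hp$ground_truth$landmarks_moving,
                            hp$ground_truth$landmarks_target)
    h <- nrow(hp$ct_slice); w <- ncol(hp$ct_slice)
    gx <- rep(seq_len(w) - 1L, each = h); gy <- rep(seq_len(h) - 1L, times = w)
    truth <- cbind(gx, gy) + hp$ground_truth$displacement(cbind(gx, gy))
    est <- warp_forward(reg$warp, cbind(gx, gy))
    err <- sqrt(rowSums((est - truth)^2))
    expect_lt(mean(err[as.vector(hp$ground_truth$tissue_mask_2d)]), 1)
  }
})
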